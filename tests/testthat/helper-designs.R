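# Shared fixtures: the base simulated designs used across tests.
# Unit-variance convention; case means set by AUC inversion.

base_null_config <- function(n = 50000, prevalence = 0.01, psi = 0.1,
                             asc1 = 0.15, asc2 = 0.50, seed = NULL) {
  trial_config(n = n, prevalence = prevalence, psi = psi,
               auc1 = 0.78, auc2 = 0.78,
               ascertainment1 = asc1, ascertainment2 = asc2, seed = seed)
}

# hypothetical oral cancer screening design: visual/tactile exam (test 1,
# almost no biopsies) vs exam + imaging adjunct (test 2, near-universal
# biopsy); under the null both AUCs sit at test 1's value with thresholds
# kept at their design (alternative-calibrated) positions
oral_demo_config <- function(null = FALSE, seed = NULL) {
  trial_config(n = 50000, prevalence = 0.01, psi = 0.1,
               auc1 = 0.77, auc2 = if (null) 0.77 else 0.71,
               calibration_auc1 = 0.77, calibration_auc2 = 0.71,
               ascertainment1 = 0.0001, ascertainment2 = 0.97, seed = seed)
}

# draw n points from params truncated to the quadrant, by rejection
rtruncated_quadrant <- function(n, params, thr, quadrant) {
  out <- matrix(numeric(0), 0, 2)
  while (nrow(out) < n) {
    z1 <- rnorm(3 * n)
    z2 <- params$rho * z1 + sqrt(1 - params$rho^2) * rnorm(3 * n)
    x <- cbind(params$mu1 + sqrt(params$var1) * z1,
               params$mu2 + sqrt(params$var2) * z2)
    out <- rbind(out, x[quadrant_of(x, thr) == quadrant, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

params_vec <- function(p) c(p$mu1, p$mu2, p$var1, p$var2, p$rho)
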