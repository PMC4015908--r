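#' Full area under the binormal ROC curve
#'
#' Under the binormal model the full AUC of a test with Gaussian case and
#' non-case score distributions is
#' `Phi((mu_case - mu_noncase) / sqrt(var_case + var_noncase))`.
#'
#' @param case_mu,case_var Mean and variance of the case score distribution.
#' @param noncase_mu,noncase_var Mean and variance of the non-case score
#'   distribution.
#' @return The AUC, a value in (0, 1); 0.5 when the means are equal.
#' @examples
#' binormal_auc(sqrt(2) * qnorm(0.78), 1, 0, 1)  # 0.78
#' @export
binormal_auc <- function(case_mu, case_var, noncase_mu, noncase_var) {
  if (any(c(case_var, noncase_var) <= 0))
    stop("variances must be strictly positive", call. = FALSE)
  pnorm((case_mu - noncase_mu) / sqrt(case_var + noncase_var))
}

# Delta-method variances and covariance of the two estimated binormal AUCs
# in the paired design. AUC_j = Phi(d_j), d_j = (mu_j1 - mu_j0) / tau_j,
# tau_j^2 = var_j1 + var_j0 (1 = cases, 0 = non-cases). For Gaussian data
# the sample moments satisfy
#   Var(mean_j)  = var_j / n,      Cov(mean_1, mean_2)   = rho s_1 s_2 / n,
#   Var(var_j)   = 2 var_j^2 / n,  Cov(var_1, var_2)     = 2 rho^2 var_1 var_2 / n,
# means independent of variances, so with partials
#   dA/dmu_1 = phi(d)/tau, dA/dvar = -phi(d) d / (2 tau^2)
# the variances and the between-test covariance follow. Case and non-case
# contributions add (independent samples).
auc_delta_cov <- function(case, noncase, n_cases, n_noncases) {
  v1 <- c(case$var1, case$var2); v0 <- c(noncase$var1, noncase$var2)
  tau2 <- v1 + v0
  d <- c(case$mu1 - noncase$mu1, case$mu2 - noncase$mu2) / sqrt(tau2)
  ph <- dnorm(d)
  V <- ph^2 * ((v1 / n_cases + v0 / n_noncases) / tau2 +
                 d^2 / (4 * tau2^2) * (2 * v1^2 / n_cases + 2 * v0^2 / n_noncases))
  C <- ph[1] * ph[2] *
    ((case$rho * sqrt(v1[1] * v1[2]) / n_cases +
        noncase$rho * sqrt(v0[1] * v0[2]) / n_noncases) / sqrt(tau2[1] * tau2[2]) +
       d[1] * d[2] / (4 * tau2[1] * tau2[2]) *
         (2 * case$rho^2 * v1[1] * v1[2] / n_cases +
            2 * noncase$rho^2 * v0[1] * v0[2] / n_noncases))
  list(V1 = V[1], V2 = V[2], C = C)
}

# Obuchowski-McClish variance function for the full binormal AUC,
# VF(A) = 0.0099 exp(-a^2/2) * ((5 a^2 + 8) + (a^2 + 8) / R),
# a = sqrt(2) Phi^{-1}(A), R = n_noncases / n_cases; variance = VF / n_cases.
# Derived for rating-scale data, it exceeds the continuous-data delta-method
# variance away from A = 0.5 and yields the conservative behaviour of the
# AUC-difference test seen in screening trial practice.
auc_var_obuchowski <- function(auc, n_cases, n_noncases) {
  a <- sqrt(2) * qnorm(auc)
  R <- n_noncases / n_cases
  0.0099 * exp(-a^2 / 2) * ((5 * a^2 + 8) + (a^2 + 8) / R) / n_cases
}

#' Test of the paired difference in full binormal AUCs
#'
#' Computes both tests' full binormal AUCs from class parameter sets shared
#' across tests (the paired design), the variance of the AUC difference, and
#' a two-sided z test of no difference.
#'
#' Two variance estimators are available. `"obuchowski"` (the default) uses
#' the Obuchowski-McClish variance function of the full binormal AUC for
#' each test, with the between-test correlation of the AUC estimates taken
#' from the delta-method covariance induced by the case and non-case score
#' correlations. `"delta"` uses the exact delta-method variance of the
#' difference; it is asymptotically correct for continuous Gaussian scores
#' and therefore less conservative.
#'
#' @param case_params,noncase_params [bvn_params()] for the case and
#'   non-case score distributions (test 1 is the first margin).
#' @param n_cases,n_noncases Effective numbers of cases and non-cases behind
#'   the parameter estimates; both must be at least 2.
#' @param alpha Two-sided significance level (default 0.05).
#' @param var_method `"obuchowski"` or `"delta"` (see Details).
#' @return An object of class `"auc_test"`: list with `auc1`, `auc2`,
#'   `diff` (= auc1 - auc2), `var_diff`, `z`, `p`, `reject`, `winner`
#'   (1 or 2 when rejecting, else `NA`), `alpha`, `valid`. When the variance
#'   is non-positive or non-finite the test is flagged `valid = FALSE`
#'   rather than silently dropped.
#' @examples
#' cp <- bvn_params(1.09, 1.09, 1, 1, 0.1)
#' np <- bvn_params(0, 0, 1, 1, 0.1)
#' auc_difference_test(cp, np, 500, 49500)
#' @export
auc_difference_test <- function(case_params, noncase_params, n_cases, n_noncases,
                                alpha = 0.05,
                                var_method = c("obuchowski", "delta")) {
  var_method <- match.arg(var_method)
  stopifnot(inherits(case_params, "bvn_params"),
            inherits(noncase_params, "bvn_params"))
  if (n_cases < 2 || n_noncases < 2)
    stop("need at least two cases and two non-cases", call. = FALSE)
  auc1 <- binormal_auc(case_params$mu1, case_params$var1,
                       noncase_params$mu1, noncase_params$var1)
  auc2 <- binormal_auc(case_params$mu2, case_params$var2,
                       noncase_params$mu2, noncase_params$var2)
  dc <- auc_delta_cov(case_params, noncase_params, n_cases, n_noncases)
  if (var_method == "delta") {
    var_diff <- dc$V1 + dc$V2 - 2 * dc$C
  } else {
    r <- dc$C / sqrt(dc$V1 * dc$V2)
    V1 <- auc_var_obuchowski(auc1, n_cases, n_noncases)
    V2 <- auc_var_obuchowski(auc2, n_cases, n_noncases)
    var_diff <- V1 + V2 - 2 * r * sqrt(V1 * V2)
  }
  d <- auc1 - auc2
  valid <- is.finite(var_diff) && var_diff > 0
  if (valid) {
    z <- d / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  } else {
    z <- p <- NA_real_
  }
  reject <- valid && p < alpha
  structure(list(auc1 = auc1, auc2 = auc2, diff = d, var_diff = var_diff,
                 z = z, p = p, reject = reject,
                 winner = if (reject) if (d > 0) 1L else 2L else NA_integer_,
                 alpha = alpha, var_method = var_method, valid = valid),
            class = "auc_test")
}

#' @export
print.auc_test <- function(x, ...) {
  cat(sprintf("Binormal AUCs: test 1 = %.4f, test 2 = %.4f (diff %+.4f)\n",
              x$auc1, x$auc2, x$diff))
  if (x$valid) {
    cat(sprintf("z = %.3f, two-sided p = %.4g (%s variance, alpha = %g)\n",
                x$z, x$p, x$var_method, x$alpha))
    if (x$reject) cat(sprintf("Reject: test %d looks superior\n", x$winner))
    else cat("No significant difference\n")
  } else {
    cat("Test invalid: variance of the AUC difference not positive/finite\n")
  }
  invisible(x)
}
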