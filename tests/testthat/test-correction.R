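test_that("partition assigns cases to quadrants with the >= convention", {
  thr <- thresholds(1, -0.5)
  x <- rbind(c(2, 0.5),      # both at/above -> Q1, set A
             c(0, -1.5),     # both below    -> Q4, set B
             c(1, -1.5),     # exactly at a1 -> Q2, set A
             c(0.99, -0.5))  # exactly at a2 -> Q3, set A
  part <- partition_cases(x, thr)
  expect_identical(part$quadrant, c(1L, 4L, 2L, 3L))
  expect_equal(nrow(part$set_a), 3)
  expect_equal(nrow(part$set_b), 1)
  expect_equal(unname(part$set_b[1, ]), c(0, -1.5))
  expect_equal(vapply(part$quadrant_members, nrow, 0L),
               c(Q1 = 1L, Q2 = 1L, Q3 = 1L, Q4 = 1L))
})

test_that("without truncation the quadrant MLE is the sample MLE", {
  set.seed(41)
  x <- cbind(rnorm(400, 1, 1.3), rnorm(400, -0.5, 0.8))
  thr <- thresholds(-Inf, -Inf)
  fit <- nath_estimate(x, 1, thr)
  s <- compute_sample_stats(x, ml = TRUE)
  expect_true(attr(fit, "converged"))
  expect_equal(fit$mu1, s$mean1, tolerance = 1e-3)
  expect_equal(fit$mu2, s$mean2, tolerance = 1e-3)
  expect_equal(fit$var1, s$sd1^2, tolerance = 1e-2)
  expect_equal(fit$var2, s$sd2^2, tolerance = 1e-2)
  expect_equal(fit$rho, s$corr, tolerance = 1e-2)
})

test_that("quadrant-truncated MLE recovers the generating parameters", {
  set.seed(43)
  p <- bvn_params(1.092, 0.910, 1, 1, 0.1)
  thr <- thresholds(1.092, 0.910)
  x <- rtruncated_quadrant(20000, p, thr, 4)
  fit <- nath_estimate(x, 4, thr)
  expect_true(attr(fit, "converged"))
  expect_lt(max(abs(params_vec(fit) - params_vec(p))), 0.05)
})

test_that("quadrants with fewer than two points are skipped", {
  thr <- thresholds(0, 0)
  expect_null(nath_estimate(matrix(c(1, 1), 1), 1, thr))
  expect_null(nath_estimate(matrix(numeric(0), 0, 2), 1, thr))
})

test_that("candidate selection maximises the untruncated likelihood", {
  set.seed(47)
  p_true <- bvn_params(1.092, 0.910, 1, 1, 0.1)
  x <- cbind(rnorm(10000) + 1.092, rnorm(10000) * sqrt(1 - 0.01))
  x[, 2] <- 0.910 + 0.1 * (x[, 1] - 1.092) + x[, 2] * 1 # rho = 0.1 approx
  p_off <- bvn_params(2.092, 0.910, 1, 1, 0.1)          # mean off by 1 SD
  sel <- select_nath(list(Q2 = p_off, Q4 = p_true), x)
  expect_identical(sel$quadrant, "Q4")
  expect_identical(sel$params, p_true)
  # single candidate passes through; ties break in quadrant order
  expect_identical(select_nath(list(Q3 = p_off), x)$quadrant, "Q3")
  sel_tie <- select_nath(list(Q4 = p_true, Q1 = p_true, Q2 = p_true), x)
  expect_identical(sel_tie$quadrant, "Q1")
  expect_error(select_nath(list(), x), "no quadrant")
})

test_that("the sampling fraction follows the bivariate normal tail", {
  p <- bvn_params(0, 0, 1, 1, 0)
  expect_equal(sampling_fraction(p, thresholds(-Inf, -Inf)), 1)
  expect_equal(sampling_fraction(p, thresholds(Inf, Inf)), 0)
  expect_equal(sampling_fraction(p, thresholds(0, 0)), 0.75, tolerance = 1e-12)
  # monotone non-increasing in each threshold
  p2 <- bvn_params(1.1, 0.9, 1.2, 0.9, 0.3)
  grid <- seq(-3, 3, by = 0.5)
  lam_a1 <- vapply(grid, function(a) sampling_fraction(p2, thresholds(a, 0.2)), 0)
  lam_a2 <- vapply(grid, function(a) sampling_fraction(p2, thresholds(0.2, a)), 0)
  expect_true(all(diff(lam_a1) <= 1e-12))
  expect_true(all(diff(lam_a2) <= 1e-12))
})

test_that("weighting collapses to one set at extreme sampling fractions", {
  set.seed(53)
  a <- cbind(rnorm(30, 2), rnorm(30, 1))
  b <- cbind(rnorm(25, -1), rnorm(25, 0.5))
  sa <- compute_sample_stats(a, ml = TRUE)
  sb <- compute_sample_stats(b, ml = TRUE)
  w1 <- weighted_estimates(1, sa, sb)
  expect_equal(params_vec(w1),
               c(sa$mean1, sa$mean2, sa$sd1^2, sa$sd2^2, sa$corr),
               tolerance = 1e-12)
  w0 <- weighted_estimates(0, sa, sb)
  expect_equal(params_vec(w0),
               c(sb$mean1, sb$mean2, sb$sd1^2, sb$sd2^2, sb$corr),
               tolerance = 1e-12)
})

test_that("weighting with the realized fraction reproduces pooled ML moments", {
  # brute-force oracle: for random small datasets split by random
  # thresholds, weighting the within-set ML moments by |A|/n must equal
  # the pooled full-sample ML moments exactly
  set.seed(59)
  for (i in 1:1000) {
    n <- sample(6:40, 1)
    x <- cbind(rnorm(n, runif(1, -1, 1)), rnorm(n, runif(1, -1, 1), sd = runif(1, 0.5, 2)))
    thr <- thresholds(stats::quantile(x[, 1], runif(1, 0.2, 0.8)),
                      stats::quantile(x[, 2], runif(1, 0.2, 0.8)))
    part <- partition_cases(x, thr)
    if (nrow(part$set_a) < 2 || nrow(part$set_b) < 2) next
    lam <- nrow(part$set_a) / n
    w <- weighted_estimates(lam,
                            compute_sample_stats(part$set_a, ml = TRUE),
                            compute_sample_stats(part$set_b, ml = TRUE))
    pooled <- compute_sample_stats(x, ml = TRUE)
    expect_equal(params_vec(w),
                 c(pooled$mean1, pooled$mean2, pooled$sd1^2, pooled$sd2^2,
                   pooled$corr),
                 tolerance = 1e-10)
  }
})

test_that("full correction without missing cases returns the case sample MLE", {
  cfg <- trial_config(n = 20000, prevalence = 0.1, psi = 0,
                      thresholds = thresholds(-Inf, -Inf))
  tr <- simulate_trial(cfg, seed = 61)
  res <- correct_case_params(tr)
  expect_true(res$converged)
  expect_false(res$weighted)               # set B is empty
  expect_equal(res$lambda_hat, 1)
  mle <- compute_sample_stats(tr[tr$true_case, c("x1", "x2")], ml = TRUE)
  expect_equal(params_vec(res$params),
               c(mle$mean1, mle$mean2, mle$sd1^2, mle$sd2^2, mle$corr),
               tolerance = 5e-3)
})

test_that("correction falls back to Nath estimates when set B is too small", {
  # psi = 0 and high ascertainment leave (almost) no interval cases
  cfg <- trial_config(n = 4000, prevalence = 0.1, psi = 0,
                      auc1 = 0.78, auc2 = 0.78,
                      ascertainment1 = 0.995, ascertainment2 = 0.995)
  set.seed(67)
  for (i in 1:20) {
    tr <- simulate_trial(cfg)
    res <- correct_case_params(tr)
    if (res$n_set_b <= 1) {
      expect_false(res$weighted)
      expect_true(res$converged)
      expect_identical(res$params, res$nath_params)
      break
    }
  }
})

test_that("correction of a fixed dataset is bit-reproducible", {
  tr <- simulate_trial(base_null_config(n = 20000, prevalence = 0.02), seed = 71)
  expect_identical(correct_case_params(tr), correct_case_params(tr))
})

test_that("correction fails loudly with too few observed cases", {
  df <- data.frame(id = 1:3, x1 = c(5, -1, -1), x2 = c(5, -1, -1),
                   true_case = c(TRUE, FALSE, FALSE),
                   symptomatic = FALSE,
                   observed_case = c(TRUE, FALSE, FALSE))
  tr <- structure(df, config = list(thresholds = thresholds(1, 1)),
                  class = c("trial_data", "data.frame"))
  res <- correct_case_params(tr)
  expect_false(res$converged)
  expect_null(res$params)
})

test_that("correction shrinks the bias of the case parameter estimates", {
  # base design with differential ascertainment: observed-case means are
  # biased upward; corrected means must be closer to the truth on average
  cfg <- base_null_config(prevalence = 0.14, asc1 = 0.15, asc2 = 0.8)
  truth <- cfg$case_params
  set.seed(73)
  reps <- 200
  obs_mu <- corr_mu <- matrix(NA_real_, reps, 2)
  corr_auc <- matrix(NA_real_, reps, 2)
  for (i in seq_len(reps)) {
    tr <- simulate_trial(cfg)
    so <- sample_stats_by_status(tr, "observed", "case")
    res <- correct_case_params(tr)
    if (!res$converged) next
    obs_mu[i, ] <- c(so$mean1, so$mean2)
    corr_mu[i, ] <- c(res$params$mu1, res$params$mu2)
    sn <- sample_stats_by_status(tr, "observed", "noncase")
    corr_auc[i, ] <- c(
      binormal_auc(res$params$mu1, res$params$var1, sn$mean1, sn$sd1^2),
      binormal_auc(res$params$mu2, res$params$var2, sn$mean2, sn$sd2^2))
  }
  ok <- !is.na(corr_mu[, 1])
  expect_gt(mean(ok), 0.9)
  bias_obs <- abs(colMeans(obs_mu[ok, ]) - c(truth$mu1, truth$mu2))
  bias_corr <- abs(colMeans(corr_mu[ok, ]) - c(truth$mu1, truth$mu2))
  expect_true(all(bias_corr < bias_obs))
  # corrected AUCs sit near the true 0.78 on average
  expect_lt(max(abs(colMeans(corr_auc[ok, ]) - 0.78)), 0.03)
})
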