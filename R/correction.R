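#' Sample statistics of paired scores
#'
#' Means, standard deviations and correlation of a set of score pairs.
#' With `ml = TRUE` the variance and covariance use the count (maximum
#' likelihood) denominator `n` instead of `n - 1`; the sampling-fraction
#' weighting uses ML denominators so that its moment-pooling identity holds
#' exactly.
#'
#' @param x Two-column matrix (or data frame with `x1`, `x2`) of score pairs.
#' @param ml Use count denominators for second moments? Default `FALSE`.
#' @return An object of class `"sample_stats"`: list with `mean1`, `mean2`,
#'   `sd1`, `sd2`, `corr`, `count`.
#' @export
compute_sample_stats <- function(x, ml = FALSE) {
  x <- as_score_matrix(x)
  n <- nrow(x)
  if (n < 1L) stop("need at least one observation", call. = FALSE)
  m <- colMeans(x)
  if (ml) {
    v <- colMeans(x^2) - m^2
    cv <- mean(x[, 1] * x[, 2]) - m[1] * m[2]
  } else {
    v <- c(var(x[, 1]), var(x[, 2]))
    cv <- if (n > 1) cov(x[, 1], x[, 2]) else NA_real_
  }
  r <- if (n > 1 && all(v > 0)) cv / sqrt(v[1] * v[2]) else NA_real_
  structure(list(mean1 = m[[1]], mean2 = m[[2]],
                 sd1 = sqrt(max(v[1], 0)), sd2 = sqrt(max(v[2], 0)),
                 corr = unname(r), count = n),
            class = "sample_stats")
}

# sample_stats -> bvn_params (fails informatively on degenerate input)
stats_to_params <- function(s) {
  bvn_params(s$mean1, s$mean2, s$sd1^2, s$sd2^2, s$corr)
}

#' Partition observed cases by the threshold quadrants
#'
#' Splits observed-case score pairs into set A (at least one score at/above
#' its threshold of suspicion: quadrants 1-3, the screen-detected region)
#' and set B (both scores below: quadrant 4, the interval-case region), and
#' records quadrant membership.
#'
#' @param x Two-column matrix of observed-case score pairs.
#' @param thr A [thresholds()] object with finite entries.
#' @return An object of class `"partitioned_cases"`: list with `set_a`,
#'   `set_b` (matrices), `quadrant` (integer vector in 1..4 per row of `x`)
#'   and `quadrant_members` (list of four matrices).
#' @export
partition_cases <- function(x, thr) {
  stopifnot(inherits(thr, "thresholds"))
  x <- as_score_matrix(x)
  q <- quadrant_of(x, thr)
  members <- lapply(1:4, function(i) x[q == i, , drop = FALSE])
  names(members) <- paste0("Q", 1:4)
  structure(list(set_a = x[q != 4L, , drop = FALSE],
                 set_b = x[q == 4L, , drop = FALSE],
                 quadrant = q, quadrant_members = members,
                 thresholds = thr),
            class = "partitioned_cases")
}

#' Maximum likelihood estimation from one truncated quadrant
#'
#' Estimates the five bivariate Gaussian parameters from score pairs that
#' all lie inside a single quadrant of the threshold partition, by direct
#' numerical maximisation of the truncated log-likelihood
#' ([truncated_bvn_loglik()]). The optimisation is parameterised with log
#' standard deviations and an atanh correlation so iterates stay feasible,
#' is initialised at the quadrant sample statistics, and is polished with a
#' quasi-Newton step; `converged` is reported on the result. Quadrants with
#' fewer than two points carry no variance information and return `NULL`.
#'
#' @param x Two-column matrix of score pairs, all inside `quadrant`.
#' @param quadrant Integer in 1..4.
#' @param thr A [thresholds()] object.
#' @param tol Convergence tolerance on the objective (relative) for the
#'   polishing step; default 1e-6.
#' @param max_iter Iteration cap per optimisation stage; default 500.
#' @return A [bvn_params()] object with attributes `converged` (logical)
#'   and `loglik` (the maximised truncated log-likelihood), or `NULL` when
#'   fewer than two points are available.
#' @export
nath_estimate <- function(x, quadrant, thr, tol = 1e-6, max_iter = 500) {
  x <- as_score_matrix(x)
  if (nrow(x) < 2L) return(NULL)
  quadrant <- as.integer(quadrant)
  if (any(quadrant_of(x, thr) != quadrant))
    stop("all points must lie inside the stated quadrant", call. = FALSE)
  s <- compute_sample_stats(x, ml = TRUE)
  v1 <- max(s$sd1^2, 1e-8); v2 <- max(s$sd2^2, 1e-8)
  r0 <- if (is.finite(s$corr)) min(max(s$corr, -0.99), 0.99) else 0
  init <- c(s$mean1, s$mean2, 0.5 * log(v1), 0.5 * log(v2), atanh(r0))
  # quadrant thresholds may be infinite in degenerate designs; the C++
  # objective handles the limits through the CDF
  fit <- optim(init, tbvn_negloglik_cpp, x1 = x[, 1], x2 = x[, 2],
               a1 = thr$a1, a2 = thr$a2, q = quadrant,
               method = "Nelder-Mead",
               control = list(maxit = 10L * max_iter, reltol = 1e-10))
  polish <- tryCatch(
    optim(fit$par, tbvn_negloglik_cpp, x1 = x[, 1], x2 = x[, 2],
          a1 = thr$a1, a2 = thr$a2, q = quadrant,
          method = "BFGS", control = list(maxit = max_iter, reltol = tol^2)),
    error = function(e) fit)
  best <- if (polish$value <= fit$value) polish else fit
  if (best$value >= 1e11) {
    out <- stats_to_params(s)
    attr(out, "converged") <- FALSE
    attr(out, "loglik") <- -Inf
    return(out)
  }
  out <- bvn_params(best$par[1], best$par[2],
                    exp(2 * best$par[3]), exp(2 * best$par[4]),
                    tanh(best$par[5]))
  attr(out, "converged") <- (polish$convergence == 0 || fit$convergence == 0)
  attr(out, "loglik") <- -best$value
  out
}

#' Choose among quadrant-specific estimates
#'
#' From the candidate parameter sets fitted per quadrant, selects the one
#' maximising the log-likelihood of the full (untruncated) bivariate
#' Gaussian over all observed case scores. Ties break in quadrant order
#' Q1 < Q2 < Q3 < Q4.
#'
#' @param candidates Named list (`"Q1"`..`"Q4"`, any subset) of
#'   [bvn_params()] candidates.
#' @param x Two-column matrix of all observed case score pairs.
#' @return List with `quadrant` (name) and `params`.
#' @export
select_nath <- function(candidates, x) {
  if (length(candidates) == 0L)
    stop("no quadrant candidates available", call. = FALSE)
  ord <- order(match(names(candidates), paste0("Q", 1:4)))
  candidates <- candidates[ord]
  ll <- vapply(candidates, bvn_loglik, numeric(1), x = x)
  best <- which.max(ll)   # first maximum = lowest quadrant on ties
  list(quadrant = names(candidates)[best], params = candidates[[best]])
}

#' Estimated sampling fraction of set A
#'
#' The estimated probability that a case has at least one score at/above
#' its threshold, `lambda = 1 - Phi2((a1 - mu1)/sd1, (a2 - mu2)/sd2, rho)`,
#' evaluated at the selected quadrant estimates.
#'
#' @param params A [bvn_params()] object (the Nath estimates).
#' @param thr A [thresholds()] object.
#' @return A probability in \[0, 1\].
#' @export
sampling_fraction <- function(params, thr) {
  stopifnot(inherits(params, "bvn_params"), inherits(thr, "thresholds"))
  p <- bvn_cdf((thr$a1 - params$mu1) / sqrt(params$var1),
               (thr$a2 - params$mu2) / sqrt(params$var2), params$rho)
  min(max(1 - p, 0), 1)
}

#' Sampling-fraction weighted estimates
#'
#' Combines the set A and set B sample moments into weighted estimates of
#' the case-score mean, variance and correlation. With weight `lambda` on
#' set A:
#' \deqn{\mu_j = \lambda \bar{X}_{j,A} + (1-\lambda) \bar{X}_{j,B}}
#' \deqn{\sigma_j^2 = G_j + H_j - \mu_j^2, \quad
#'       G_j = \lambda(\bar{X}_{j,A}^2 + S_{j,A}^2), \quad
#'       H_j = (1-\lambda)(\bar{X}_{j,B}^2 + S_{j,B}^2)}
#' \deqn{\rho = (P + Q - \mu_1 \mu_2) / (\sigma_1 \sigma_2), \quad
#'       P = \lambda(\bar{X}_{1,A}\bar{X}_{2,A} + S_{1,A} S_{2,A} r_A), \quad
#'       Q = (1-\lambda)(\bar{X}_{1,B}\bar{X}_{2,B} + S_{1,B} S_{2,B} r_B)}
#' (the conditional-mean/variance/covariance decomposition over the A/B
#' partition). When the within-set moments use count denominators and
#' `lambda` equals the realized fraction `|A| / (|A| + |B|)`, the weighted
#' estimates reproduce the pooled full-sample ML moments exactly.
#'
#' @param lambda_hat Weight for set A, in \[0, 1\] (see
#'   [sampling_fraction()]).
#' @param stats_a,stats_b [compute_sample_stats()] of sets A and B
#'   (ML denominators).
#' @return A [bvn_params()] object, or `NULL` with a warning-free failure
#'   signalled via attribute: if a weighted variance is non-positive or the
#'   weighted correlation falls outside \[-1, 1\] the function returns
#'   `NULL` (correction failure for this dataset).
#' @export
weighted_estimates <- function(lambda_hat, stats_a, stats_b) {
  stopifnot(inherits(stats_a, "sample_stats"), inherits(stats_b, "sample_stats"))
  if (!is.finite(lambda_hat) || lambda_hat < 0 || lambda_hat > 1)
    stop("lambda_hat must lie in [0, 1]", call. = FALSE)
  la <- lambda_hat; lb <- 1 - lambda_hat
  mu1 <- la * stats_a$mean1 + lb * stats_b$mean1
  mu2 <- la * stats_a$mean2 + lb * stats_b$mean2
  G1 <- la * (stats_a$mean1^2 + stats_a$sd1^2)
  H1 <- lb * (stats_b$mean1^2 + stats_b$sd1^2)
  G2 <- la * (stats_a$mean2^2 + stats_a$sd2^2)
  H2 <- lb * (stats_b$mean2^2 + stats_b$sd2^2)
  v1 <- G1 + H1 - mu1^2
  v2 <- G2 + H2 - mu2^2
  P <- la * (stats_a$mean1 * stats_a$mean2 +
               stats_a$sd1 * stats_a$sd2 * stats_a$corr)
  Q <- lb * (stats_b$mean1 * stats_b$mean2 +
               stats_b$sd1 * stats_b$sd2 * stats_b$corr)
  if (!is.finite(v1) || !is.finite(v2) || v1 <= 0 || v2 <= 0) return(NULL)
  rho <- (P + Q - mu1 * mu2) / sqrt(v1 * v2)
  if (!is.finite(rho) || abs(rho) > 1) return(NULL)
  bvn_params(mu1, mu2, v1, v2, rho)
}

#' Bias-corrected case score distribution
#'
#' Runs the full correction on the observed cases of one trial:
#' \enumerate{
#'   \item partition the observed cases into set A (screen-detected region)
#'     and set B (interval-case region) and into the four threshold
#'     quadrants;
#'   \item fit the truncated bivariate Gaussian by maximum likelihood in
#'     every quadrant holding at least two points ([nath_estimate()]) and
#'     keep the candidate maximising the untruncated log-likelihood over
#'     all observed cases ([select_nath()]);
#'   \item estimate the sampling fraction of set A from those estimates
#'     ([sampling_fraction()]) and combine the set A and set B sample
#'     moments by sampling-fraction weighting ([weighted_estimates()]).
#' }
#' If set A or set B holds at most one observation the weighting is skipped
#' and the selected quadrant estimates serve as the corrected estimates.
#' If no quadrant admits a converged fit, or the weighting produces an
#' infeasible parameter set, the correction fails for this dataset and is
#' flagged (never silently imputed).
#'
#' @param data A `"trial_data"` object (or any data frame with `x1`, `x2`,
#'   `observed_case`).
#' @param thr Thresholds; defaults to the ones in the trial configuration.
#' @param tol,max_iter Passed to [nath_estimate()].
#' @return An object of class `"correction_result"`: list with `params`
#'   (corrected [bvn_params()] or `NULL`), `lambda_hat`, `winning_quadrant`,
#'   `weighted`, `converged`, `n_observed`, `n_set_a`, `n_set_b`,
#'   `n_quadrant` (integer vector), `n_cases_estimated` (set A count divided
#'   by the sampling fraction, clamped to \[observed cases, n\]) and
#'   `nath_params` (the selected quadrant estimates).
#' @export
correct_case_params <- function(data, thr = NULL, tol = 1e-6, max_iter = 500) {
  if (is.null(thr)) thr <- attr(data, "config")$thresholds
  if (is.null(thr)) stop("thresholds required", call. = FALSE)
  oc <- as_score_matrix(data[data$observed_case, c("x1", "x2")])
  n_total <- nrow(data)
  failed <- function(part) {
    structure(list(params = NULL, lambda_hat = NA_real_,
                   winning_quadrant = NA_character_, weighted = FALSE,
                   converged = FALSE, n_observed = nrow(oc),
                   n_set_a = if (is.null(part)) NA_integer_ else nrow(part$set_a),
                   n_set_b = if (is.null(part)) NA_integer_ else nrow(part$set_b),
                   n_quadrant = if (is.null(part)) rep(NA_integer_, 4)
                                else vapply(part$quadrant_members, nrow, 0L),
                   n_cases_estimated = NA_real_, nath_params = NULL),
              class = "correction_result")
  }
  if (nrow(oc) < 2L) return(failed(NULL))
  part <- partition_cases(oc, thr)
  candidates <- list()
  for (q in 1:4) {
    xq <- part$quadrant_members[[q]]
    if (nrow(xq) < 2L) next
    fit <- tryCatch(nath_estimate(xq, q, thr, tol = tol, max_iter = max_iter),
                    error = function(e) NULL)
    if (!is.null(fit) && isTRUE(attr(fit, "converged")))
      candidates[[paste0("Q", q)]] <- fit
  }
  if (length(candidates) == 0L) return(failed(part))
  sel <- select_nath(candidates, oc)
  lam <- sampling_fraction(sel$params, thr)
  n_hat <- if (lam > 0)
    min(max(nrow(part$set_a) / lam, nrow(oc)), n_total) else nrow(oc)
  if (nrow(part$set_a) <= 1L || nrow(part$set_b) <= 1L) {
    params <- sel$params; weighted <- FALSE
  } else {
    params <- weighted_estimates(lam,
                                 compute_sample_stats(part$set_a, ml = TRUE),
                                 compute_sample_stats(part$set_b, ml = TRUE))
    weighted <- TRUE
    if (is.null(params)) {          # infeasible weighted moments
      out <- failed(part)
      out$lambda_hat <- lam
      out$winning_quadrant <- sel$quadrant
      out$nath_params <- sel$params
      return(out)
    }
  }
  structure(list(params = params, lambda_hat = lam,
                 winning_quadrant = sel$quadrant, weighted = weighted,
                 converged = TRUE, n_observed = nrow(oc),
                 n_set_a = nrow(part$set_a), n_set_b = nrow(part$set_b),
                 n_quadrant = vapply(part$quadrant_members, nrow, 0L),
                 n_cases_estimated = n_hat, nath_params = sel$params),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  if (!x$converged) {
    cat("Bias correction failed (no usable quadrant fit or infeasible weighting)\n")
    return(invisible(x))
  }
  cat(sprintf("Bias-corrected case distribution (%s, quadrant %s, lambda_hat = %.3f):\n",
              if (x$weighted) "weighted" else "Nath estimates only",
              x$winning_quadrant, x$lambda_hat))
  print(x$params)
  cat(sprintf("Observed cases: %d (set A %d, set B %d); estimated total cases: %.0f\n",
              x$n_observed, x$n_set_a, x$n_set_b, x$n_cases_estimated))
  invisible(x)
}
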