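#' Bivariate Gaussian parameter set for one disease class
#'
#' Bundles the means, variances and correlation of the pair of screening
#' test scores within one disease class (cases or non-cases).
#'
#' @param mu1,mu2 Means of the scores on test 1 and test 2 (score units).
#' @param var1,var2 Variances of the scores; must be strictly positive.
#' @param rho Correlation between the two scores, in \[-1, 1\].
#'
#' @return An object of class `"bvn_params"`: a list with elements `mu1`,
#'   `mu2`, `var1`, `var2`, `rho`.
#' @examples
#' bvn_params(1.09, 0.91, 1, 1, 0.1)
#' @export
bvn_params <- function(mu1, mu2, var1 = 1, var2 = 1, rho = 0) {
  vals <- c(mu1, mu2, var1, var2, rho)
  if (length(vals) != 5L || !all(is.finite(vals)))
    stop("bvn_params requires five finite scalars", call. = FALSE)
  if (var1 <= 0 || var2 <= 0)
    stop("variances must be strictly positive", call. = FALSE)
  if (abs(rho) > 1)
    stop("|rho| must not exceed 1", call. = FALSE)
  structure(list(mu1 = mu1, mu2 = mu2, var1 = var1, var2 = var2, rho = rho),
            class = "bvn_params")
}

#' @export
print.bvn_params <- function(x, ...) {
  cat(sprintf("Bivariate Gaussian: mu = (%.4f, %.4f), var = (%.4f, %.4f), rho = %.4f\n",
              x$mu1, x$mu2, x$var1, x$var2, x$rho))
  invisible(x)
}

#' Thresholds of suspicion
#'
#' The score thresholds that trigger referral to the reference standard
#' test. A score at or above its threshold is suspicious. Infinite values
#' are allowed for degenerate designs (`-Inf`: every participant referred;
#' `+Inf`: no referrals through that test).
#'
#' @param a1,a2 Thresholds for test 1 and test 2.
#' @return An object of class `"thresholds"`.
#' @export
thresholds <- function(a1, a2) {
  if (length(a1) != 1L || length(a2) != 1L || is.na(a1) || is.na(a2))
    stop("thresholds must be two non-missing scalars", call. = FALSE)
  structure(list(a1 = as.numeric(a1), a2 = as.numeric(a2)), class = "thresholds")
}

#' @export
print.thresholds <- function(x, ...) {
  cat(sprintf("Thresholds of suspicion: a1 = %g, a2 = %g\n", x$a1, x$a2))
  invisible(x)
}

#' Standard bivariate normal distribution function
#'
#' `P(Z1 <= h, Z2 <= k)` for a standard bivariate normal vector with
#' correlation `rho`, computed with Genz's double-precision quadrature
#' (absolute accuracy better than 1e-14). Arguments are recycled.
#'
#' @param h,k Upper integration limits; `-Inf`/`+Inf` allowed.
#' @param rho Correlation in \[-1, 1\].
#' @return Numeric vector of probabilities.
#' @examples
#' bvn_cdf(0, 0, 0)            # 0.25
#' bvn_cdf(0, 0, 0.5)          # 1/4 + asin(0.5) / (2 * pi) = 1/3
#' @export
bvn_cdf <- function(h, k, rho) {
  if (any(is.na(rho)) || any(abs(rho) > 1))
    stop("rho must lie in [-1, 1]", call. = FALSE)
  bvn_cdf_cpp(as.numeric(h), as.numeric(k), as.numeric(rho))
}

#' Quadrant membership of paired scores
#'
#' Assigns each score pair to one of the four quadrants cut by the two
#' thresholds of suspicion. The comparison is `>=`: a score exactly at its
#' threshold counts as suspicious.
#'
#' Quadrant 1: both scores at/above; quadrant 2: test 1 only; quadrant 3:
#' test 2 only; quadrant 4: both below.
#'
#' @param x Two-column numeric matrix of score pairs.
#' @param thr A [thresholds()] object.
#' @return Integer vector in 1..4.
#' @export
quadrant_of <- function(x, thr) {
  x <- as_score_matrix(x)
  ifelse(x[, 1] >= thr$a1,
         ifelse(x[, 2] >= thr$a2, 1L, 2L),
         ifelse(x[, 2] >= thr$a2, 3L, 4L))
}

#' Probability of a screening quadrant
#'
#' Probability that a score pair drawn from `params` falls into the given
#' quadrant of the threshold partition.
#'
#' @param params A [bvn_params()] object.
#' @param thr A [thresholds()] object.
#' @param quadrant Integer in 1..4 (see [quadrant_of()]).
#' @return A probability.
#' @export
quadrant_prob <- function(params, thr, quadrant) {
  stopifnot(inherits(params, "bvn_params"), inherits(thr, "thresholds"))
  quadrant <- as.integer(quadrant)
  if (length(quadrant) != 1L || quadrant < 1L || quadrant > 4L)
    stop("quadrant must be a single integer in 1..4", call. = FALSE)
  quad_prob_cpp(params$mu1, params$mu2, sqrt(params$var1), sqrt(params$var2),
                params$rho, thr$a1, thr$a2, quadrant)
}

#' Log-likelihood of an untruncated bivariate Gaussian sample
#'
#' @param params A [bvn_params()] object.
#' @param x Two-column matrix of score pairs.
#' @return The log-likelihood (scalar).
#' @export
bvn_loglik <- function(params, x) {
  x <- as_score_matrix(x)
  s1 <- sqrt(params$var1); s2 <- sqrt(params$var2); r <- params$rho
  if (abs(r) >= 1) return(-Inf)
  z1 <- (x[, 1] - params$mu1) / s1
  z2 <- (x[, 2] - params$mu2) / s2
  sum(-log(2 * pi) - log(s1) - log(s2) - 0.5 * log1p(-r^2) -
        (z1^2 - 2 * r * z1 * z2 + z2^2) / (2 * (1 - r^2)))
}

#' Log-likelihood of a quadrant-truncated bivariate Gaussian sample
#'
#' Log-likelihood of `x` under the bivariate Gaussian `params` restricted
#' to one quadrant of the threshold partition, i.e. the density normalised
#' by the quadrant probability. All points must lie inside the quadrant.
#' Returns `-Inf` when the quadrant probability underflows to zero, which
#' signals infeasible parameters to an optimiser.
#'
#' @inheritParams quadrant_prob
#' @param x Two-column matrix of score pairs inside the quadrant.
#' @return The truncated log-likelihood (scalar, possibly `-Inf`).
#' @export
truncated_bvn_loglik <- function(params, x, quadrant, thr) {
  x <- as_score_matrix(x)
  quadrant <- as.integer(quadrant)
  if (any(quadrant_of(x, thr) != quadrant))
    stop("all points must lie inside the stated quadrant", call. = FALSE)
  p <- quadrant_prob(params, thr, quadrant)
  if (!is.finite(p) || p <= 0) return(-Inf)
  bvn_loglik(params, x) - nrow(x) * log(p)
}

# coerce scores to a two-column numeric matrix
as_score_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("x1", "x2")])
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("paired scores must have two columns", call. = FALSE)
  storage.mode(x) <- "double"
  x
}
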