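#' Median allowed agreement of two zero rates
#'
#' For marginal zero probabilities `p1` and `p2` the joint zero probability
#' `q` is constrained to the Frechet interval
#' `[max(0, p1 + p2 - 1), min(p1, p2)]`; this returns its midpoint, the
#' default joint rate used for zero-inflated simulations.
#'
#' @param p1,p2 Marginal zero probabilities in \[0, 1\].
#' @return The midpoint of the feasible interval for `q`.
#' @examples
#' median_allowed_agreement(0.5, 0.5)  # 0.25
#' median_allowed_agreement(0.9, 0.9)  # 0.85
#' @export
median_allowed_agreement <- function(p1, p2) {
  stopifnot(all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1))
  (pmax(0, p1 + p2 - 1) + pmin(p1, p2)) / 2
}

#' Zero-inflation configuration for one disease class
#'
#' @param p1,p2 Marginal probabilities that the test 1 / test 2 score is
#'   replaced by zero.
#' @param q Joint probability that both scores are replaced; defaults to
#'   the [median_allowed_agreement()] of the marginals. Must satisfy the
#'   Frechet bounds.
#' @return An object of class `"zero_weight_config"`.
#' @export
zero_weight_config <- function(p1, p2, q = median_allowed_agreement(p1, p2)) {
  if (p1 < 0 || p1 > 1 || p2 < 0 || p2 > 1)
    stop("marginal zero rates must lie in [0, 1]", call. = FALSE)
  lo <- max(0, p1 + p2 - 1); hi <- min(p1, p2)
  if (q < lo - 1e-12 || q > hi + 1e-12)
    stop(sprintf("infeasible joint zero rate q = %g (allowed [%g, %g])",
                 q, lo, hi), call. = FALSE)
  structure(list(p1 = p1, p2 = p2, q = q), class = "zero_weight_config")
}

# correlated Bernoulli pair with marginals (p1, p2) and joint q, drawn from
# the four-cell joint distribution {q, p1-q, p2-q, 1-p1-p2+q}
draw_zero_pair <- function(n, zw) {
  u <- runif(n)
  both <- u < zw$q
  only1 <- !both & u < zw$p1
  only2 <- !both & !only1 & u < zw$p1 + zw$p2 - zw$q
  cbind(z1 = both | only1, z2 = both | only2)
}

#' Zero-inflate the scores of a simulated trial
#'
#' Emulates imaging-style data in which readers score "no disease seen" as
#' an exact zero: per participant a correlated Bernoulli pair (marginals
#' `p1`, `p2`, joint `q` for that participant's true class) decides which
#' scores are replaced by 0.0. Observed status is re-derived from the
#' modified scores and the original symptom flags.
#'
#' @param data A [simulate_trial()] result.
#' @param case_zero,noncase_zero [zero_weight_config()] objects for cases
#'   and non-cases.
#' @param seed Optional seed for the Bernoulli draws.
#' @return A `"trial_data"` object with modified scores.
#' @export
apply_zero_inflation <- function(data, case_zero, noncase_zero, seed = NULL) {
  stopifnot(inherits(data, "trial_data"),
            inherits(case_zero, "zero_weight_config"),
            inherits(noncase_zero, "zero_weight_config"))
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(FALSE, nrow(data), 2)
  ic <- data$true_case
  z[ic, ] <- draw_zero_pair(sum(ic), case_zero)
  z[!ic, ] <- draw_zero_pair(sum(!ic), noncase_zero)
  data$x1[z[, 1]] <- 0
  data$x2[z[, 2]] <- 0
  refresh_observed_status(data)
}

#' Bin the scores of a simulated trial
#'
#' Replaces every score by the centre of its bin, with half-open bins
#' `[m * width, (m + 1) * width)` aligned at zero, producing multinomial
#' score data. Observed status is re-derived from the binned scores.
#'
#' @param data A [simulate_trial()] result.
#' @param bin_width Positive bin width (score units; the Gaussian designs
#'   use fractions of the score standard deviation).
#' @return A `"trial_data"` object with binned scores.
#' @examples
#' \dontrun{bin_scores(simulate_trial(cfg), bin_width = 0.25)}
#' @export
bin_scores <- function(data, bin_width) {
  stopifnot(inherits(data, "trial_data"))
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("bin_width must be strictly positive", call. = FALSE)
  data$x1 <- (floor(data$x1 / bin_width) + 0.5) * bin_width
  data$x2 <- (floor(data$x2 / bin_width) + 0.5) * bin_width
  refresh_observed_status(data)
}

# re-derive observed status after a score transformation; symptom flags
# are untouched
refresh_observed_status <- function(data) {
  thr <- attr(data, "config")$thresholds
  data$observed_case <- derive_observed_status(data$x1, data$x2,
                                               data$true_case,
                                               data$symptomatic, thr)
  data
}
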