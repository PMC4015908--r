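#' Case mean achieving a target binormal AUC
#'
#' Inverts the full binormal AUC for the case mean:
#' `mu = noncase_mu + sqrt(case_var + noncase_var) * qnorm(target_auc)`.
#' Used to set up simulated designs whose true AUCs are fixed.
#'
#' @param target_auc Target full AUC in (0, 1); values at or above 0.5 keep
#'   the convention that cases score higher.
#' @param case_var,noncase_var Score variances (default 1).
#' @param noncase_mu Non-case mean (default 0).
#' @return The case mean.
#' @examples
#' calibrate_case_mean(0.78)  # sqrt(2) * qnorm(0.78)
#' @export
calibrate_case_mean <- function(target_auc, case_var = 1, noncase_mu = 0,
                                noncase_var = 1) {
  if (!is.finite(target_auc) || target_auc <= 0 || target_auc >= 1)
    stop("target_auc must lie strictly between 0 and 1", call. = FALSE)
  if (case_var <= 0 || noncase_var <= 0)
    stop("variances must be strictly positive", call. = FALSE)
  noncase_mu + sqrt(case_var + noncase_var) * qnorm(target_auc)
}

#' Threshold of suspicion achieving a target percent ascertainment
#'
#' Places the threshold at the upper `target_ascertainment` quantile of the
#' case score distribution, so that the stated fraction of cases scores at
#' or above it: `a = case_mu + sqrt(case_var) * qnorm(1 - target)`.
#' Targets of 0 and 1 return the `+Inf` / `-Inf` sentinels.
#'
#' @param target_ascertainment Target fraction of cases at/above the
#'   threshold, in \[0, 1\].
#' @param case_mu,case_var Case score mean and variance.
#' @return The threshold (possibly infinite).
#' @examples
#' calibrate_threshold(0.5, 1.09)          # the case median
#' calibrate_threshold(0.8, 0, 1)          # -qnorm(0.8) = -0.8416
#' @export
calibrate_threshold <- function(target_ascertainment, case_mu, case_var = 1) {
  if (!is.finite(target_ascertainment) ||
      target_ascertainment < 0 || target_ascertainment > 1)
    stop("target_ascertainment must lie in [0, 1]", call. = FALSE)
  if (case_var <= 0) stop("case_var must be strictly positive", call. = FALSE)
  if (target_ascertainment == 0) return(Inf)
  if (target_ascertainment == 1) return(-Inf)
  case_mu + sqrt(case_var) * qnorm(1 - target_ascertainment)
}
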