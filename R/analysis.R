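#' Sample statistics by disease status definition
#'
#' Paired-score sample statistics over the cases or non-cases of one trial,
#' under either the true or the observed disease status definition.
#'
#' @param data A `"trial_data"` object.
#' @param status `"true"` (omniscient) or `"observed"` (study investigator).
#' @param class `"case"` or `"noncase"`.
#' @param ml Use count denominators for second moments? Default `FALSE`.
#' @return A [compute_sample_stats()] result.
#' @export
sample_stats_by_status <- function(data, status = c("true", "observed"),
                                   class = c("case", "noncase"), ml = FALSE) {
  status <- match.arg(status); class <- match.arg(class)
  flag <- if (status == "true") data$true_case else data$observed_case
  keep <- if (class == "case") flag else !flag
  if (sum(keep) < 2L)
    stop(sprintf("fewer than two %s %ss in this trial", status, class),
         call. = FALSE)
  compute_sample_stats(data[keep, c("x1", "x2")], ml = ml)
}

#' Analyze one trial: true, observed or corrected
#'
#' Runs one of the three competing analyses of a paired screening trial,
#' each ending in the two-sided test of no difference in full binormal
#' AUCs ([auc_difference_test()]):
#' \describe{
#'   \item{true}{case and non-case sample statistics under the true status
#'     (the omniscient analysis, available only in simulation);}
#'   \item{observed}{sample statistics under the observed status (the
#'     standard analysis actually available to the investigator);}
#'   \item{corrected}{case parameters from [correct_case_params()] combined
#'     with the observed non-case statistics -- the correction adjusts
#'     sensitivity only, specificity is left uncorrected.}
#' }
#' The corrected analysis evaluates the test variance at the estimated
#' total number of cases (set A count / sampling fraction) because the
#' corrected parameters describe the full case population, not only the
#' observed cases.
#'
#' @param data A `"trial_data"` object.
#' @param mode `"true"`, `"observed"` or `"corrected"`.
#' @param alpha Two-sided significance level (default 0.05).
#' @param var_method Passed to [auc_difference_test()].
#' @param correction Optional precomputed [correct_case_params()] result
#'   (avoids refitting when several modes are run on one trial).
#' @return An object of class `"analysis_result"`: list with `mode`, `test`
#'   (an `"auc_test"` or `NULL`), `winner`, `case_params_used`,
#'   `noncase_params_used`, `n_cases_used`, `n_noncases_used`, `valid`, and
#'   for the corrected mode the `correction` provenance.
#' @export
analyze_trial <- function(data, mode = c("true", "observed", "corrected"),
                          alpha = 0.05,
                          var_method = c("obuchowski", "delta"),
                          correction = NULL) {
  mode <- match.arg(mode)
  var_method <- match.arg(var_method)
  stopifnot(inherits(data, "trial_data"))
  invalid <- function(corr = NULL) {
    structure(list(mode = mode, test = NULL, winner = NA_integer_,
                   case_params_used = NULL, noncase_params_used = NULL,
                   n_cases_used = NA_integer_, n_noncases_used = NA_integer_,
                   valid = FALSE, correction = corr),
              class = "analysis_result")
  }
  status <- if (mode == "true") "true" else "observed"
  res <- tryCatch({
    noncase <- stats_to_params(sample_stats_by_status(data, status, "noncase"))
    n0 <- if (status == "true") sum(!data$true_case) else sum(!data$observed_case)
    corr <- NULL
    if (mode == "corrected") {
      corr <- if (!is.null(correction)) correction else correct_case_params(data)
      if (!corr$converged) return(invalid(corr))
      case <- corr$params
      n1 <- round(corr$n_cases_estimated)
    } else {
      case <- stats_to_params(sample_stats_by_status(data, status, "case"))
      n1 <- if (status == "true") sum(data$true_case) else sum(data$observed_case)
    }
    test <- auc_difference_test(case, noncase, n1, n0, alpha = alpha,
                                var_method = var_method)
    structure(list(mode = mode, test = test, winner = test$winner,
                   case_params_used = case, noncase_params_used = noncase,
                   n_cases_used = n1, n_noncases_used = n0,
                   valid = test$valid, correction = corr),
              class = "analysis_result")
  }, error = function(e) invalid())
  res
}

#' @export
print.analysis_result <- function(x, ...) {
  cat(sprintf("%s analysis", x$mode))
  if (!x$valid) {
    cat(": invalid for this trial\n")
    return(invisible(x))
  }
  cat(sprintf(" (%d cases, %d non-cases used)\n", x$n_cases_used,
              x$n_noncases_used))
  print(x$test)
  invisible(x)
}
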