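#' Configuration of a simulated paired screening trial
#'
#' Assembles all design parameters of one simulated trial. Class score
#' distributions default to the unit-variance convention: non-cases are
#' standard bivariate Gaussian with correlation `rho_noncase`; case means
#' are set by [calibrate_case_mean()] so the true full AUCs equal `auc1`
#' and `auc2`. Thresholds of suspicion are placed by [calibrate_threshold()]
#' at the case-score quantiles giving the target percent ascertainment;
#' `calibration_auc1`/`calibration_auc2` allow the thresholds to be
#' calibrated against a different (e.g. planned-alternative) case
#' distribution than the one simulated, since in a real trial the referral
#' thresholds are fixed design properties. Explicit `case_params`,
#' `noncase_params` or `thresholds` override the calibrated defaults.
#'
#' @param n Number of participants.
#' @param prevalence Disease prevalence, in (0, 1).
#' @param psi Probability that a true case shows signs and symptoms during
#'   follow-up (interval-case rate); non-cases never do.
#' @param auc1,auc2 True full binormal AUCs of tests 1 and 2.
#' @param rho_case,rho_noncase Score correlations within cases / non-cases.
#' @param ascertainment1,ascertainment2 Target fractions of cases scoring
#'   at/above each test's threshold.
#' @param calibration_auc1,calibration_auc2 AUCs whose case distribution is
#'   used to place the thresholds (defaults: the true AUCs).
#' @param case_params,noncase_params Optional [bvn_params()] overrides.
#' @param thresholds Optional [thresholds()] override.
#' @param seed Optional integer seed stored with the configuration.
#' @return An object of class `"trial_config"`.
#' @examples
#' cfg <- trial_config(n = 50000, prevalence = 0.01, psi = 0.1,
#'                     auc1 = 0.78, auc2 = 0.78,
#'                     ascertainment1 = 0.15, ascertainment2 = 0.50)
#' @export
trial_config <- function(n, prevalence, psi = 0.1,
                         auc1 = 0.78, auc2 = 0.78,
                         rho_case = 0.1, rho_noncase = 0.1,
                         ascertainment1 = 0.5, ascertainment2 = 0.5,
                         calibration_auc1 = auc1, calibration_auc2 = auc2,
                         case_params = NULL, noncase_params = NULL,
                         thresholds = NULL, seed = NULL) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie strictly between 0 and 1", call. = FALSE)
  if (psi < 0 || psi > 1) stop("psi must lie in [0, 1]", call. = FALSE)
  if (is.null(noncase_params))
    noncase_params <- bvn_params(0, 0, 1, 1, rho_noncase)
  if (is.null(case_params))
    case_params <- bvn_params(
      calibrate_case_mean(auc1, 1, noncase_params$mu1, noncase_params$var1),
      calibrate_case_mean(auc2, 1, noncase_params$mu2, noncase_params$var2),
      1, 1, rho_case)
  if (is.null(thresholds)) {
    cal1 <- calibrate_case_mean(calibration_auc1, 1, noncase_params$mu1,
                                noncase_params$var1)
    cal2 <- calibrate_case_mean(calibration_auc2, 1, noncase_params$mu2,
                                noncase_params$var2)
    thresholds <- thresholds(
      calibrate_threshold(ascertainment1, cal1, 1),
      calibrate_threshold(ascertainment2, cal2, 1))
  }
  structure(list(n = as.integer(n), prevalence = prevalence, psi = psi,
                 case_params = case_params, noncase_params = noncase_params,
                 thresholds = thresholds, seed = seed),
            class = "trial_config")
}

#' @export
print.trial_config <- function(x, ...) {
  cat(sprintf("Paired screening trial design: n = %d, prevalence = %g, psi = %g\n",
              x$n, x$prevalence, x$psi))
  cat("Cases:    "); print(x$case_params)
  cat("Non-cases:"); print(x$noncase_params)
  print(x$thresholds)
  invisible(x)
}

#' Read a trial configuration from a YAML or JSON file
#'
#' Recognised keys: `n`, `prevalence`, `psi`, `auc1`, `auc2`, `rho_case`,
#' `rho_noncase`, `ascertainment1`, `ascertainment2`, `seed`, and optional
#' `a1`/`a2` which override the calibrated thresholds.
#'
#' @param path File path; format chosen by extension (`.json` vs
#'   `.yaml`/`.yml`).
#' @return A [trial_config()] object.
#' @export
trial_config_from_file <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  # YAML 1.1 scalar rules turn the bare key `n` into a boolean; restore it
  names(cfg)[names(cfg) %in% c("FALSE", "F")] <- "n"
  args <- cfg[names(cfg) %in% c("n", "prevalence", "psi", "auc1", "auc2",
                                "rho_case", "rho_noncase",
                                "ascertainment1", "ascertainment2", "seed")]
  if (!is.null(cfg$a1) || !is.null(cfg$a2)) {
    if (is.null(cfg$a1) || is.null(cfg$a2))
      stop("threshold override needs both a1 and a2", call. = FALSE)
    args$thresholds <- thresholds(cfg$a1, cfg$a2)
  }
  do.call(trial_config, args)
}

# correlated bivariate Gaussian draws for one class
rbvn_pairs <- function(n, params) {
  z1 <- rnorm(n)
  z2 <- params$rho * z1 + sqrt(1 - params$rho^2) * rnorm(n)
  cbind(x1 = params$mu1 + sqrt(params$var1) * z1,
        x2 = params$mu2 + sqrt(params$var2) * z2)
}

# observed disease status implied by scores, thresholds and symptoms:
# a true case is observed iff referred (a score at/above its threshold)
# or symptomatic during follow-up; non-cases are never observed as cases
# (the reference standard is perfectly specific).
derive_observed_status <- function(x1, x2, true_case, symptomatic, thr) {
  true_case & (x1 >= thr$a1 | x2 >= thr$a2 | symptomatic)
}

#' Simulate one paired screening trial
#'
#' Draws the number of cases `M ~ Binomial(n, prevalence)`, paired case and
#' non-case scores from the configured bivariate Gaussian distributions, a
#' symptom indicator (`Bernoulli(psi)`, cases only), and derives each
#' participant's observed disease status: a case is observed if at least
#' one score is at/above its threshold of suspicion or if signs and
#' symptoms appear during follow-up. All other cases are misclassified as
#' non-cases.
#'
#' @param config A [trial_config()] object.
#' @param seed Optional seed overriding `config$seed`; with a fixed seed the
#'   result is reproducible bit for bit.
#' @return An object of class `"trial_data"`: a data frame with columns
#'   `id`, `x1`, `x2`, `true_case`, `symptomatic`, `observed_case` and
#'   attributes `config` and `m_true`.
#' @export
simulate_trial <- function(config, seed = NULL) {
  stopifnot(inherits(config, "trial_config"))
  seed <- if (!is.null(seed)) seed else config$seed
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  m <- rbinom(1L, n, config$prevalence)
  cases <- rbvn_pairs(m, config$case_params)
  noncases <- rbvn_pairs(n - m, config$noncase_params)
  x1 <- c(cases[, 1], noncases[, 1])
  x2 <- c(cases[, 2], noncases[, 2])
  true_case <- rep(c(TRUE, FALSE), c(m, n - m))
  symptomatic <- logical(n)
  if (m > 0) symptomatic[seq_len(m)] <- runif(m) < config$psi
  observed <- derive_observed_status(x1, x2, true_case, symptomatic,
                                     config$thresholds)
  out <- data.frame(id = seq_len(n), x1 = x1, x2 = x2,
                    true_case = true_case, symptomatic = symptomatic,
                    observed_case = observed)
  structure(out, config = config, m_true = m,
            class = c("trial_data", "data.frame"))
}

#' @export
print.trial_data <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Paired screening trial: %d participants, %d true cases, %d observed cases\n",
              nrow(x), sum(x$true_case), sum(x$observed_case)))
  if (!is.null(cfg$thresholds))
    cat(sprintf("(%d interval cases, %d misclassified cases)\n",
                sum(x$observed_case & x$x1 < cfg$thresholds$a1 & x$x2 < cfg$thresholds$a2),
                sum(x$true_case & !x$observed_case)))
  invisible(x)
}

#' Realized percent ascertainment of a test
#'
#' 100 times the number of observed cases scoring at/above the test's
#' threshold of suspicion, divided by the number of observed cases.
#'
#' @param data A [simulate_trial()] result.
#' @param test_index 1 or 2.
#' @return A percentage in \[0, 100\].
#' @export
percent_ascertainment <- function(data, test_index) {
  stopifnot(inherits(data, "trial_data"), test_index %in% c(1, 2))
  thr <- attr(data, "config")$thresholds
  obs <- data[data$observed_case, , drop = FALSE]
  if (nrow(obs) == 0L)
    stop("percent ascertainment undefined: no observed cases", call. = FALSE)
  a <- if (test_index == 1) thr$a1 else thr$a2
  s <- if (test_index == 1) obs$x1 else obs$x2
  100 * sum(s >= a) / nrow(obs)
}

#' Write / read trial data as CSV
#'
#' The file holds the columns `id, x1, x2, true_case, symptomatic,
#' observed_case` (flags as 0/1) with a header row; missing values are not
#' permitted. `read_trial_csv()` restores a `"trial_data"` object; the
#' thresholds must be re-supplied since the CSV carries only the data.
#'
#' @param data A `"trial_data"` object.
#' @param path File path.
#' @rdname trial_csv
#' @export
write_trial_csv <- function(data, path) {
  stopifnot(inherits(data, "trial_data"))
  out <- data.frame(id = data$id, x1 = data$x1, x2 = data$x2,
                    true_case = as.integer(data$true_case),
                    symptomatic = as.integer(data$symptomatic),
                    observed_case = as.integer(data$observed_case))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param thr A [thresholds()] object to attach on read (optional; needed
#'   by the correction and by [percent_ascertainment()]).
#' @rdname trial_csv
#' @export
read_trial_csv <- function(path, thr = NULL) {
  x <- read.csv(path)
  need <- c("id", "x1", "x2", "true_case", "symptomatic", "observed_case")
  if (!all(need %in% names(x)))
    stop("trial CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyNA(x[need])) stop("trial CSV must not contain missing values",
                           call. = FALSE)
  x$true_case <- as.logical(x$true_case)
  x$symptomatic <- as.logical(x$symptomatic)
  x$observed_case <- as.logical(x$observed_case)
  cfg <- if (!is.null(thr)) list(thresholds = thr) else NULL
  structure(x, config = cfg, m_true = sum(x$true_case),
            class = c("trial_data", "data.frame"))
}
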