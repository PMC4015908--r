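#' Configuration of one Monte Carlo simulation cell
#'
#' A cell is one point of the simulation design: a trial configuration, a
#' number of replicates, a significance level and an optional non-Gaussian
#' variant. Replicate seeds are drawn once from the cell seed, so cells are
#' reproducible and order-independent.
#'
#' @param n_reps Number of replicate trials.
#' @param alpha Significance level of the AUC-difference test.
#' @param seed Cell seed (integer).
#' @param variant `"gaussian"` (default), `"multinomial"` (scores binned
#'   with `bin_width`) or `"zero_inflated"` (scores zeroed per
#'   `case_zero` / `noncase_zero`).
#' @param bin_width Bin width for the multinomial variant.
#' @param case_zero,noncase_zero [zero_weight_config()] objects for the
#'   zero-inflated variant.
#' @param var_method Variance estimator for the AUC-difference test.
#' @param ... Passed to [trial_config()] (n, prevalence, psi, auc1, auc2,
#'   rho_case, rho_noncase, ascertainment1, ascertainment2, ...).
#' @return An object of class `"cell_config"`.
#' @examples
#' cc <- cell_config(n_reps = 10, seed = 1, n = 5000, prevalence = 0.14,
#'                   ascertainment1 = 0.5, ascertainment2 = 0.8)
#' @export
cell_config <- function(n_reps, ..., alpha = 0.05, seed = 1,
                        variant = c("gaussian", "multinomial", "zero_inflated"),
                        bin_width = NULL, case_zero = NULL, noncase_zero = NULL,
                        var_method = c("obuchowski", "delta")) {
  variant <- match.arg(variant)
  var_method <- match.arg(var_method)
  if (n_reps < 1) stop("n_reps must be at least 1", call. = FALSE)
  if (variant == "multinomial" && (is.null(bin_width) || bin_width <= 0))
    stop("multinomial variant requires a positive bin_width", call. = FALSE)
  if (variant == "zero_inflated" &&
      (!inherits(case_zero, "zero_weight_config") ||
       !inherits(noncase_zero, "zero_weight_config")))
    stop("zero_inflated variant requires zero_weight_config for both classes",
         call. = FALSE)
  structure(list(trial = trial_config(...), n_reps = as.integer(n_reps),
                 alpha = alpha, seed = as.integer(seed), variant = variant,
                 bin_width = bin_width, case_zero = case_zero,
                 noncase_zero = noncase_zero, var_method = var_method),
            class = "cell_config")
}

#' Run one Monte Carlo cell
#'
#' Simulates `n_reps` independent trials, applies the true, observed and
#' corrected analyses to each, and aggregates decision-error metrics per
#' mode: the rejection rate (the Type I error rate under a null cell, power
#' under an alternative), the correct rejection fraction (test rejects and
#' the estimated winner is the truly superior test), the wrong rejection
#' fraction (test rejects but picks the truly inferior test), the mean
#' estimated AUC difference, the correction/analysis failure rate, and a
#' binomial Monte Carlo standard error of the rejection rate. Under a null
#' cell (equal true AUCs) the correct/wrong fractions are reported as `NA`.
#' Replicates whose correction fails are excluded from the corrected-mode
#' denominators but counted in `failure_rate`.
#'
#' @param config A [cell_config()] object.
#' @param verbose Print progress every 100 replicates? Default `FALSE`.
#' @return An object of class `"cell_result"`: a data frame with one row
#'   per mode and columns `mode`, `n_valid`, `rejection_rate`,
#'   `correct_rejection_fraction`, `wrong_rejection_fraction`, `mean_diff`,
#'   `failure_rate`, `monte_carlo_se`; the per-replicate table is attached
#'   as attribute `replicates`.
#' @export
run_cell <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "cell_config"))
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max, config$n_reps)
  modes <- c("true", "observed", "corrected")
  tc <- config$trial
  true_auc1 <- binormal_auc(tc$case_params$mu1, tc$case_params$var1,
                            tc$noncase_params$mu1, tc$noncase_params$var1)
  true_auc2 <- binormal_auc(tc$case_params$mu2, tc$case_params$var2,
                            tc$noncase_params$mu2, tc$noncase_params$var2)
  superior <- if (true_auc1 == true_auc2) NA_integer_
              else if (true_auc1 > true_auc2) 1L else 2L
  reps <- vector("list", config$n_reps)
  for (i in seq_len(config$n_reps)) {
    set.seed(rep_seeds[i])
    trial <- simulate_trial(tc, seed = NULL)
    trial <- switch(config$variant,
      gaussian = trial,
      multinomial = bin_scores(trial, config$bin_width),
      zero_inflated = apply_zero_inflation(trial, config$case_zero,
                                           config$noncase_zero))
    corr <- correct_case_params(trial)
    row <- lapply(modes, function(m) {
      a <- analyze_trial(trial, m, alpha = config$alpha,
                         var_method = config$var_method,
                         correction = if (m == "corrected") corr else NULL)
      data.frame(rep = i, mode = m, valid = a$valid,
                 diff = if (a$valid) a$test$diff else NA_real_,
                 p = if (a$valid) a$test$p else NA_real_,
                 reject = isTRUE(a$valid) && a$test$reject,
                 winner = if (a$valid) a$test$winner else NA_integer_)
    })
    reps[[i]] <- do.call(rbind, row)
    if (verbose && i %% 100 == 0)
      message(sprintf("  replicate %d / %d", i, config$n_reps))
  }
  reps <- do.call(rbind, reps)
  out <- do.call(rbind, lapply(modes, function(m) {
    r <- reps[reps$mode == m, , drop = FALSE]
    nv <- sum(r$valid)
    if (nv == 0L) stop(sprintf("all replicates invalid for mode %s", m),
                       call. = FALSE)
    rv <- r[r$valid, , drop = FALSE]
    rej <- mean(rv$reject)
    data.frame(mode = m, n_valid = nv, rejection_rate = rej,
               correct_rejection_fraction = if (is.na(superior)) NA_real_
                 else mean(rv$reject & !is.na(rv$winner) & rv$winner == superior),
               wrong_rejection_fraction = if (is.na(superior)) NA_real_
                 else mean(rv$reject & !is.na(rv$winner) & rv$winner != superior),
               mean_diff = mean(rv$diff),
               failure_rate = 1 - nv / nrow(r),
               monte_carlo_se = sqrt(rej * (1 - rej) / nv))
  }))
  structure(out, replicates = reps, config = config, superior = superior,
            class = c("cell_result", "data.frame"))
}

#' @export
print.cell_result <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Monte Carlo cell: %d replicates, alpha = %g, variant = %s\n",
              cfg$n_reps, cfg$alpha, cfg$variant))
  if (is.na(attr(x, "superior")))
    cat("Null cell (equal true AUCs): rejection rate = Type I error\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Run a grid of Monte Carlo cells
#'
#' Runs each cell independently (per-cell seeds make the results
#' order-independent) and binds the per-mode summaries into one tidy table,
#' prefixed with the generating parameters. A failing cell is recorded with
#' `error` filled in and the sweep continues.
#'
#' @param configs List of [cell_config()] objects.
#' @param verbose Report per-cell progress to stderr? Default `TRUE`.
#' @return Data frame with one row per (cell, mode).
#' @export
sweep_cells <- function(configs, verbose = TRUE) {
  stopifnot(length(configs) >= 1)
  out <- lapply(seq_along(configs), function(i) {
    cc <- configs[[i]]
    described <- tryCatch({
      tc <- cc$trial
      list(base = data.frame(cell = i, n = tc$n, prevalence = tc$prevalence,
                             psi = tc$psi, a1 = tc$thresholds$a1,
                             a2 = tc$thresholds$a2, n_reps = cc$n_reps,
                             seed = cc$seed, variant = cc$variant),
           res = run_cell(cc))
    }, error = function(e) e)
    if (inherits(described, "error")) {
      if (verbose)
        message(sprintf("cell %d failed: %s", i, conditionMessage(described)))
      return(data.frame(cell = i, mode = NA_character_,
                        error = conditionMessage(described)))
    }
    base <- described$base; res <- described$res
    if (verbose)
      message(sprintf("cell %d done (%d reps; corrected failure rate %.3f)",
                      i, cc$n_reps, res$failure_rate[res$mode == "corrected"]))
    cbind(base, as.data.frame(res), error = NA_character_)
  })
  nm <- unique(unlist(lapply(out, names)))
  out <- lapply(out, function(d) { d[setdiff(nm, names(d))] <- NA; d[nm] })
  do.call(rbind, out)
}
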