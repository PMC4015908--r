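test_that("calibration helpers invert their targets", {
  expect_equal(calibrate_case_mean(0.5), 0)
  expect_equal(calibrate_case_mean(0.78), sqrt(2) * qnorm(0.78))
  expect_equal(calibrate_case_mean(0.74), sqrt(2) * qnorm(0.74))
  # round trip through the AUC
  for (a in c(0.55, 0.7, 0.9, 0.99)) {
    mu <- calibrate_case_mean(a, 2.3, 0.4, 0.9)
    expect_equal(binormal_auc(mu, 2.3, 0.4, 0.9), a, tolerance = 1e-10)
  }
  expect_error(calibrate_case_mean(1.1), "between")

  expect_equal(calibrate_threshold(0.5, 1.7), 1.7)
  expect_equal(calibrate_threshold(0.8, 0, 1), qnorm(0.2), tolerance = 1e-12)
  expect_equal(calibrate_threshold(0.15, 0, 1), qnorm(0.85), tolerance = 1e-12)
  expect_identical(calibrate_threshold(0, 0), Inf)
  expect_identical(calibrate_threshold(1, 0), -Inf)
})

test_that("observed cases are a subset of true cases and statuses obey the design", {
  cfg <- base_null_config(n = 20000, prevalence = 0.05, psi = 0.2, seed = 5)
  tr <- simulate_trial(cfg)
  expect_true(all(tr$true_case[tr$observed_case]))     # perfectly specific
  expect_true(all(tr$true_case[tr$symptomatic]))       # P(I | non-case) = 0
  thr <- cfg$thresholds
  should_observe <- tr$true_case &
    (tr$x1 >= thr$a1 | tr$x2 >= thr$a2 | tr$symptomatic)
  expect_identical(tr$observed_case, should_observe)
  expect_identical(attr(tr, "m_true"), sum(tr$true_case))
})

test_that("the same seed reproduces a trial bit for bit", {
  cfg <- base_null_config(n = 5000, prevalence = 0.1)
  expect_identical(simulate_trial(cfg, seed = 99), simulate_trial(cfg, seed = 99))
})

test_that("degenerate designs observe every case", {
  cfg <- trial_config(n = 20000, prevalence = 0.05, psi = 0,
                      thresholds = thresholds(-Inf, -Inf))
  tr <- simulate_trial(cfg, seed = 2)
  expect_identical(tr$observed_case, tr$true_case)
  expect_equal(percent_ascertainment(tr, 1), 100)
  expect_equal(percent_ascertainment(tr, 2), 100)

  # no referrals but perfect follow-up: every case is an interval case
  cfg2 <- trial_config(n = 20000, prevalence = 0.05, psi = 1,
                       thresholds = thresholds(Inf, Inf))
  tr2 <- simulate_trial(cfg2, seed = 3)
  expect_identical(tr2$observed_case, tr2$true_case)
})

test_that("with psi = 1 observed status equals true status at any thresholds", {
  cfg <- trial_config(n = 30000, prevalence = 0.14, psi = 1,
                      ascertainment1 = 0.15, ascertainment2 = 0.8)
  tr <- simulate_trial(cfg, seed = 11)
  expect_identical(tr$observed_case, tr$true_case)
  # with every case observed, realized percent ascertainment sits at the
  # calibration target (law of large numbers)
  expect_lt(abs(percent_ascertainment(tr, 1) - 15), 2)
  expect_lt(abs(percent_ascertainment(tr, 2) - 80), 2)
})

test_that("realized case counts follow the binomial mean", {
  cfg <- base_null_config(n = 50000, prevalence = 0.01)
  set.seed(4)
  m <- vapply(1:60, function(i) attr(simulate_trial(cfg), "m_true"), 0L)
  expect_lt(abs(mean(m) - 500), 3 * sqrt(500 * 0.99 / 60))
})

test_that("percent ascertainment counts observed cases at or above threshold", {
  df <- data.frame(id = 1:4,
                   x1 = c(1, -1, -2, 0), x2 = c(-5, -5, -5, -5),
                   true_case = c(TRUE, TRUE, TRUE, FALSE),
                   symptomatic = c(FALSE, TRUE, TRUE, FALSE),
                   observed_case = c(TRUE, TRUE, TRUE, FALSE))
  tr <- structure(df, config = list(thresholds = thresholds(0, 10)),
                  class = c("trial_data", "data.frame"))
  expect_equal(percent_ascertainment(tr, 1), 100 / 3, tolerance = 1e-12)
  tr$observed_case <- FALSE
  expect_error(percent_ascertainment(tr, 1), "no observed cases")
})

test_that("the misclassified fraction matches the truncation probability", {
  # fraction of cases missed ~ (1 - psi) * P(both scores below | case)
  cfg <- trial_config(n = 200000, prevalence = 0.14, psi = 0.1,
                      auc1 = 0.78, auc2 = 0.78,
                      ascertainment1 = 0.15, ascertainment2 = 0.5)
  tr <- simulate_trial(cfg, seed = 21)
  thr <- cfg$thresholds; cp <- cfg$case_params
  p_below <- bvn_cdf((thr$a1 - cp$mu1) / sqrt(cp$var1),
                     (thr$a2 - cp$mu2) / sqrt(cp$var2), cp$rho)
  p_missed <- (1 - cfg$psi) * p_below
  m <- sum(tr$true_case)
  missed <- sum(tr$true_case & !tr$observed_case)
  expect_lt(abs(missed / m - p_missed), 3 * sqrt(p_missed * (1 - p_missed) / m))
})

test_that("trial CSV round-trips and configs load from YAML and JSON", {
  cfg <- base_null_config(n = 2000, prevalence = 0.1)
  tr <- simulate_trial(cfg, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(tr, path)
  back <- read_trial_csv(path, thr = cfg$thresholds)
  expect_equal(back$x1, tr$x1, tolerance = 1e-12)
  expect_identical(back$observed_case, tr$observed_case)
  expect_equal(percent_ascertainment(back, 2), percent_ascertainment(tr, 2))

  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n: 1000", "prevalence: 0.14", "psi: 0.2", "auc1: 0.78",
               "auc2: 0.74", "ascertainment1: 0.5", "ascertainment2: 0.8",
               "seed: 3"), yml)
  c1 <- trial_config_from_file(yml)
  expect_equal(c1$case_params$mu2, sqrt(2) * qnorm(0.74))
  expect_equal(c1$thresholds$a1, sqrt(2) * qnorm(0.78), tolerance = 1e-12)

  jsn <- withr::local_tempfile(fileext = ".json")
  writeLines('{"n": 1000, "prevalence": 0.14, "psi": 0.2, "a1": 0.5, "a2": 1.5}', jsn)
  c2 <- trial_config_from_file(jsn)
  expect_equal(c2$thresholds$a1, 0.5)
  expect_equal(c2$thresholds$a2, 1.5)
})
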