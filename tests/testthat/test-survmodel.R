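test_that("step curves are right-continuous with correct pre-jump value", {
  sc <- step_curve(c(1, 2.5, 4), c(0.9, 0.6, 0.2), value_before_first = 1)
  expect_equal(step_eval(sc, c(0, 0.999, 1, 1.5, 2.5, 3, 4, 99)),
               c(1, 1, 0.9, 0.9, 0.6, 0.6, 0.2, 0.2))
  expect_error(step_curve(c(2, 1), c(0.5, 0.4), 1), "increasing")
  expect_error(step_curve(c(0, 1), c(0.5, 0.4), 1), "positive")
  df <- as.data.frame(sc)
  expect_equal(df$time, c(1, 2.5, 4))
  expect_equal(df$value, c(0.9, 0.6, 0.2))
})

test_that("unadjusted logistic fit equals the 2x2 closed form log(ad/bc)", {
  d <- binary_data(
    outcome = rep(c(1, 0, 1, 0), times = c(30, 20, 10, 40)),
    exposure = rep(c(1, 1, 0, 0), times = c(30, 20, 10, 40)))
  fit <- fit_logistic(d, adjust = FALSE)
  expect_equal(fit$exposure_coef, log((30 * 40) / (20 * 10)),
               tolerance = 1e-8)
  expect_equal(fit$intercept, log(10 / 40), tolerance = 1e-8)
  expect_equal(fit$n_subjects, 100L)
  expect_equal(fit$n_events, 40)
})

test_that("logistic fit validates input and flags separation by name", {
  expect_error(fit_logistic(binary_data(outcome = c(1, 1), exposure = 0:1)),
               "both outcome classes")
  expect_error(fit_logistic(binary_data(outcome = 0:1, exposure = c(1, 1))),
               "exposure is constant")
  sep <- binary_data(outcome = rep(0:1, each = 20),
                     exposure = rep(0:1, each = 20),
                     covariates = rnorm(40))
  expect_error(fit_logistic(sep), "separation.*`exposure`")
})

test_that("Cox exposure coefficient matches a brute-force partial-likelihood grid", {
  d <- toy_survival()
  fit <- fit_cox(d, adjust = FALSE, ties = "breslow")
  oracle <- grid_cox_coef(d$time, d$event, d$exposure)
  expect_lt(abs(fit$exposure_coef - oracle), 2e-4)
  # no ties, so Efron and Breslow coincide
  expect_equal(fit_cox(d, adjust = FALSE, ties = "efron")$exposure_coef,
               fit$exposure_coef, tolerance = 1e-8)
})

test_that("Breslow baseline reproduces hand-computed risk-set jumps", {
  d <- toy_survival()
  fit <- fit_cox(d, adjust = FALSE)
  b <- fit$exposure_coef
  # events at t = 1, 2, 4, 5, 7, 8; risk sets shrink as subjects exit
  jumps <- c(1 / (4 * exp(b) + 4), 1 / (3 * exp(b) + 4),
             1 / (2 * exp(b) + 3), 1 / (2 * exp(b) + 2), 1 / 2, 1)
  expected <- cumsum(jumps)
  h0 <- fit$baseline_cumhaz
  expect_s3_class(h0, "step_curve")
  expect_equal(step_eval(h0, c(1, 2, 4, 5, 7, 8)), expected, tolerance = 1e-8)
  expect_equal(step_eval(h0, 0.5), 0)
  expect_equal(breslow_baseline(fit)$values, h0$values, tolerance = 1e-12)
})

test_that("Cox fit validates input and reports monotone likelihood", {
  d <- toy_survival()
  d0 <- d; d0$event <- 0L
  expect_error(fit_cox(d0), "no events")
  expect_error(fit_cox(d, flip_event = TRUE) -> f, NA)
  d1 <- d; d1$event <- 1L
  expect_error(fit_cox(d1, flip_event = TRUE), "no censored subjects")
  dc <- d; dc$exposure <- 1
  expect_error(fit_cox(dc), "exposure is constant")
  # exposed all fail early, unexposed all survive late: coefficient diverges
  dm <- survival_data(time = c(1, 2, 3, 10, 11, 12),
                      event = c(1, 1, 1, 1, 1, 1),
                      exposure = c(1, 1, 1, 0, 0, 0))
  expect_error(fit_cox(dm, adjust = FALSE), "monotone")
})

test_that("standardized survival curves are valid and ordered by exposure", {
  cv <- simulate_covariates(400, seed = 61)
  d <- simulate_tte(scenario_spec("tte", "rct", 1, 1, n = 400L), cv, seed = 62)
  fit <- fit_cox(d, adjust = TRUE)
  s0 <- standardized_survival(fit, d, x = 0)
  s1 <- standardized_survival(fit, d, x = 1)
  for (s in list(s0, s1)) {
    expect_true(all(s$values >= 0 & s$values <= 1))
    expect_true(all(diff(s$values) <= 1e-12))
    expect_equal(s$value_before_first, 1)
  }
  # positive log hazard ratio: exposed curve lies strictly below
  expect_true(all(s1$values < s0$values))
  # single-subject weights reproduce that subject's model-based curve
  w <- c(1, rep(0, 399))
  si <- standardized_survival(fit, d, x = 1, weights = w)
  lp <- exp(fit$exposure_coef + fit$covariate_coefs[["c1"]] * d$c1[1])
  expect_equal(si$values,
               exp(-step_eval(fit$baseline_cumhaz, si$times) * lp),
               tolerance = 1e-10)
  expect_error(standardized_survival(fit, d, x = 1, weights = rep(0, 400)),
               "not all be zero")
  expect_error(standardized_survival(fit, d, x = 1, weights = w[-1]),
               "one entry per subject")
})

test_that("cloglog gap is constant for exactly proportional marginal hazards", {
  tms <- seq(0.5, 9.5, by = 0.5)
  v0 <- exp(-0.05 * tms^1.3)
  lam <- 0.8
  s0 <- step_curve(tms, v0, 1)
  s1 <- step_curve(tms, v0^exp(lam), 1)
  cc <- cloglog_parallelism(s0, s1)
  expect_equal(cc$mean_gap, lam, tolerance = 1e-10)
  expect_lt(cc$spread, 1e-10)
  # trimming excludes the extremes of the transform
  s_lo <- step_curve(tms, seq(0.999, 0.001, length.out = length(tms)), 1)
  cc2 <- cloglog_parallelism(s_lo, s_lo, trim = 0.1)
  expect_true(all(step_eval(s_lo, cc2$times) > 0.1))
})

test_that("tie jitter is deterministic, minimal and removes all ties", {
  t0 <- c(1, 2, 2, 2, 5, 5, 9)
  j1 <- margstd:::jitter_tied_times(t0, seed = 99)
  j2 <- margstd:::jitter_tied_times(t0, seed = 99)
  expect_identical(j1, j2)
  expect_false(any(duplicated(j1)))
  expect_true(all(abs(j1 - t0) <= 1e-8 * min(diff(sort(unique(t0))))))
  # untied input passes through untouched
  expect_identical(margstd:::jitter_tied_times(c(1, 2, 3), 1), c(1, 2, 3))
  # bootstrap-resample regime: many exact ties next to near-coincident
  # distinct values, where 1e-9 x (min gap) falls below double resolution
  base <- c(2.739152219150623, 2.739152219150623 + 6.5e-06, 5, 7)
  tb <- rep(base, times = c(40, 40, 5, 5))
  jb <- margstd:::jitter_tied_times(tb, seed = 123)
  expect_false(any(duplicated(jb)))
  # perturbations stay far below the smallest distinct gap
  expect_lt(max(abs(jb - tb)), 6.5e-06 / 2)
})
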