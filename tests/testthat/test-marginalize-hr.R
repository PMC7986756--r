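test_that("inverse-transform draws match a literal per-subject scan of the curve", {
  s <- c(0.8, 0.5, 0.3)
  grid <- c(1, 2, 3)
  m <- 500L
  out <- draw_times_from_curve(s, grid, m, seed = 301)
  # independent reference: first grid index where survival drops below u
  set.seed(301)
  u <- runif(m)
  ref_time <- numeric(m); ref_event <- integer(m)
  for (i in seq_len(m)) {
    l <- which(s < u[i])[1]
    if (is.na(l)) { ref_time[i] <- 3; ref_event[i] <- 0L }
    else { ref_time[i] <- grid[l]; ref_event[i] <- 1L }
  }
  expect_equal(out$time, ref_time)
  expect_equal(out$event, ref_event)
  # all non-events are administratively censored at the grid end
  expect_true(all(out$time[out$event == 0] == 3))
})

test_that("draws reproduce the discrete event-time distribution", {
  s <- c(0.8, 0.5, 0.3)
  grid <- c(1, 2, 3)
  probs <- c(0.2, 0.3, 0.2)       # P(event at t_l) = S(t_{l-1}) - S(t_l)
  m <- 200000L
  for (sampler in c("inverse_transform", "bernoulli_chain")) {
    out <- draw_times_from_curve(s, grid, m, seed = 311, sampler = sampler)
    for (l in 1:3) {
      phat <- mean(out$time == grid[l] & out$event == 1L)
      se <- sqrt(probs[l] * (1 - probs[l]) / m)
      expect_lt(abs(phat - probs[l]), 4 * se,
                label = paste(sampler, "l =", l))
    }
    expect_lt(abs(mean(out$event == 0L) - 0.3),
              4 * sqrt(0.3 * 0.7 / m), label = sampler)
  }
})

test_that("curve and grid validation errors fire", {
  expect_error(draw_times_from_curve(c(0.5, 0.8), c(1, 2), 10, 1),
               "nonincreasing|decreas")
  expect_error(draw_times_from_curve(c(0.5, 0, 0), c(1, 2, 3), 10, 1),
               "reaches 0 before the end")
  expect_error(draw_times_from_curve(c(0.8, 0.5), c(2, 1), 10, 1),
               "strictly increasing")
  expect_error(draw_times_from_curve(c(0.8, 0.5, 0.3), c(1, 2), 10, 1),
               "same length")
})

test_that("censoring overlay keeps the earlier time and resolves events correctly", {
  ev <- list(time = c(1, 3, 5, 5, 2), event = c(1L, 1L, 1L, 0L, 0L))
  cs <- list(time = c(2, 2, 6, 6, 2), event = c(1L, 1L, 1L, 1L, 1L))
  out <- overlay_censoring(ev, cs)
  expect_equal(out$time, c(1, 2, 5, 5, 2))
  # 1: event first; 2: censored first; 3: event first; 4: grid-end censoring
  # in the event arm stays censored; 5: tie goes to censoring
  expect_equal(out$event, c(1L, 0L, 1L, 0L, 0L))
  expect_error(overlay_censoring(ev, list(time = 1, event = 1L)),
               "same size")
})

test_that("censoring model is the flipped-indicator conditional Cox fit", {
  cv <- simulate_covariates(600, seed = 91)
  d <- simulate_tte(scenario_spec("tte", "rct", 1, 1, n = 600L), cv, seed = 92)
  cfit <- fit_censoring_model(d)
  expect_equal(cfit$n_events, sum(d$event == 0))
  ref <- survival::coxph(survival::Surv(time, 1 - event) ~ exposure + c1,
                         data = d)
  expect_equal(cfit$exposure_coef, unname(coef(ref)["exposure"]),
               tolerance = 1e-8)
})

test_that("covariate-free marginalization recovers the fitted conditional coefficient", {
  # without covariates the standardized curves are exactly proportional with
  # log ratio lambda-hat, so the simulation must give that number back up to
  # Monte Carlo error of order 1/sqrt(m)
  cv <- simulate_covariates(800, seed = 95)
  d <- simulate_tte(scenario_spec("tte", "rct", 1, 0, n = 800L), cv, seed = 96)
  d$c1 <- NULL
  lam <- fit_cox(d, adjust = FALSE, baseline = FALSE)$exposure_coef
  est <- marginal_log_hr(d, marginal_hr_config(m = 20000L, censoring = "none",
                                               seed = 97))
  expect_lt(abs(est$estimate - lam), 3 * est$meta$sim_se)
  expect_identical(est$estimand, "log_hr_marginal")
})

test_that("marginal log HR is reproducible and attenuated under covariate effects", {
  cv <- simulate_covariates(1000, seed = 101)
  d <- simulate_tte(scenario_spec("tte", "rct", 1, 1), cv, seed = 102)
  cfg <- marginal_hr_config(m = 2000L, seed = 103)
  e1 <- marginal_log_hr(d, cfg)
  e2 <- marginal_log_hr(d, cfg)
  expect_identical(e1$estimate, e2$estimate)
  e3 <- marginal_log_hr(d, marginal_hr_config(m = 2000L, seed = 104))
  expect_false(identical(e1$estimate, e3$estimate))
  # marginal < conditional by a wide margin in this design
  cond <- e1$meta$conditional_fit$exposure_coef
  expect_lt(e1$estimate, cond - 0.15)
  expect_gt(e1$estimate, 0)
  expect_identical(e1$method, "adjusted_marginal")
})

test_that("alternative censoring modes run and record their settings", {
  cv <- simulate_covariates(500, seed = 111)
  d <- simulate_tte(scenario_spec("tte", "rct", 1, 1, n = 500L), cv,
                    seed = 112)
  adm <- marginal_log_hr(d, marginal_hr_config(m = 1000L,
                                               censoring = "admin_only",
                                               seed = 113))
  expect_true(is.finite(adm$estimate))
  expect_identical(adm$meta$censoring, "admin_only")
  cg <- sort(d$time[d$event == 0])
  flat <- step_curve(cg, seq(0.999, 0.5, length.out = length(cg)), 1)
  ext <- marginal_log_hr(d, marginal_hr_config(
    m = 1000L, censoring = "external_curves", seed = 113,
    cens_curves = list(times = cg, s0 = flat, s1 = flat)))
  expect_true(is.finite(ext$estimate))
  expect_error(marginal_hr_config(censoring = "external_curves"),
               "requires `cens_curves`")
})

test_that("time_frame truncates the grid and refuses extrapolation", {
  cv <- simulate_covariates(500, seed = 121)
  d <- simulate_tte(scenario_spec("tte", "rct", 1, 1, n = 500L), cv,
                    seed = 122)
  est <- marginal_log_hr(d, marginal_hr_config(m = 1000L, time_frame = 5,
                                               seed = 123))
  expect_true(all(est$meta$s0$times <= 5))
  expect_lte(max(est$meta$s1$times), 5)
  expect_error(
    marginal_log_hr(d, marginal_hr_config(m = 1000L, time_frame = 50)),
    "extrapolation")
})
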