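test_that("links invert to within 1e-12 and are monotone", {
  p <- seq(0.01, 0.99, by = 0.01)
  for (nm in c("identity", "log", "logit", "cloglog", "probit",
               "complementary-log")) {
    l <- make_link(nm)
    expect_equal(l$linkinv(l$linkfun(p)), p, tolerance = 1e-12)
    expect_true(all(diff(l$linkfun(p)) > 0) || all(diff(l$linkfun(p)) < 0),
                info = nm)
  }
})

test_that("ccf_eval matches the worked logistic example and closed forms", {
  # treated probability when the untreated one is 0.047 (3 dp inputs)
  expect_equal(round(ccf_eval("logit", log(10), 0.047), 3), 0.330)
  # closed form g(x) = 10x/(1+9x)
  expect_equal(ccf_eval("logit", log(10), 0.5), 10 * 0.5 / (1 + 9 * 0.5),
               tolerance = 1e-12)
  # identity-link CCF is a shift
  expect_equal(ccf_eval("identity", 0.2, 0.3), 0.5, tolerance = 1e-12)
  expect_warning(out <- ccf_eval("identity", 0.9, 0.4),
                 "outside \\(0,1\\)")
  expect_equal(out, 1.3, tolerance = 1e-12)
  expect_error(ccf_eval("logit", 1, 1.2), "inside \\(0,1\\)")
  expect_error(ccf_eval("logit", 1, 0), "inside \\(0,1\\)")
})

test_that("CCF curvature: concave for positive, convex for negative, linear at null", {
  for (nm in c("logit", "cloglog", "probit")) {
    expect_identical(classify_ccf(nm, log(10)), "concave", label = nm)
    expect_identical(classify_ccf(nm, -2), "convex", label = nm)
    expect_identical(classify_ccf(nm, 0), "linear", label = nm)
  }
  # identity, log and complementary-log are collapsible: linear for every nu
  for (nm in c("identity", "log", "complementary-log")) {
    for (nu in c(-1, -0.3, 0, 0.4, 2)) {
      expect_identical(suppressWarnings(classify_ccf(nm, nu)), "linear",
                       label = paste(nm, nu))
    }
  }
})

test_that("discrete-time rate CCF: first interval reduces to the plain CCF", {
  for (nm in c("identity", "log")) {
    sp <- rate_model_spec(16, 1, nm, 0.3)
    for (p0 in c(0.01, 0.05, 0.2))
      expect_equal(rate_ccf_eval(sp, p0),
                   suppressWarnings(ccf_eval(nm, 0.3, p0)),
                   tolerance = 1e-12)
  }
  sp <- rate_model_spec(8, 3, "identity", 0)
  expect_equal(rate_ccf_eval(sp, 0.05), 0.05, tolerance = 1e-12)
})

test_that("rate CCF matches brute-force enumeration of the discrete process", {
  tau <- 64L; l <- 32L; lam <- 0.5; r0 <- rep(0.02, tau)
  sp <- rate_model_spec(tau, l, "log", lam, baseline_rates = r0)
  # independent enumeration: survive intervals 1..l-1, event in interval l
  p0 <- 0.02 * prod(rep(1 - 0.02, l - 1))
  r1 <- 0.02 * exp(lam)
  p1_expected <- r1 * prod(rep(1 - r1, l - 1))
  expect_equal(rate_ccf_eval(sp, p0), p1_expected, tolerance = 1e-12)
})

test_that("rate CCF rejects implied rates outside (0,1), naming the interval", {
  sp <- rate_model_spec(4, 2, "identity", 0.95,
                        baseline_rates = rep(0.2, 4))
  expect_error(rate_ccf_eval(sp, 0.16), "interval 1")
})

test_that("log-link rate model converges to the proportional-hazards risk CCF", {
  # cumulative risks under the discrete process approach
  # F1 = 1 - (1 - F0)^exp(lam) as the grid refines
  lam <- 0.7
  err <- vapply(c(32L, 512L), function(tau) {
    r <- 1 - 0.5^(1 / tau)    # constant rate, total untreated risk 0.5
    l_half <- tau %/% 2L
    f0 <- f1 <- 0
    for (l in seq_len(l_half)) {
      sp <- rate_model_spec(tau, l, "log", lam, baseline_rates = rep(r, tau))
      p0 <- r * (1 - r)^(l - 1)
      f0 <- f0 + p0
      f1 <- f1 + rate_ccf_eval(sp, p0)
    }
    abs(f1 - ccf_eval("cloglog", lam, f0))
  }, numeric(1))
  expect_lt(err[2], err[1])        # refinement shrinks the gap
  expect_lt(err[2], 1e-3)
})

test_that("quadrature oracle reproduces the worked marginal odds ratio", {
  # conditional OR 10 with C ~ U(-10,10) collapses to about 1.6 marginally
  or <- exp(marginal_effect_by_integration("logit", 0, log(10), 1,
                                           uniform_dist(-10, 10)))
  expect_equal(round(or, 2), 1.60)
  # null conditional effect is collapsible
  expect_equal(marginal_effect_by_integration("logit", 0, 0, 1,
                                              uniform_dist(-3, 3)),
               0, tolerance = 1e-10)
  # standard-normal covariate, unit effects: marginal log OR about 0.86
  expect_equal(marginal_effect_by_integration("logit", 1, 1, 1,
                                              normal_dist(0, 1)),
               0.8606, tolerance = 1e-3)
})

test_that("identity and log links are exactly collapsible under integration", {
  for (nm in c("identity", "log")) {
    for (nu in c(-0.05, 0.02)) {
      for (dist in list(uniform_dist(0.05, 0.2), normal_dist(0.1, 0.02))) {
        # small intercept/effect ranges keep probabilities valid
        me <- marginal_effect_by_integration(nm, log(0.1), nu, 0.3, dist)
        expect_equal(me, nu, tolerance = 1e-8, label = nm)
      }
    }
  }
})

test_that("noncollapsible links attenuate: marginal effect strictly inside (0, nu)", {
  for (nm in c("logit", "cloglog", "probit")) {
    for (nu in c(0.5, 1.5)) {
      me <- marginal_effect_by_integration(nm, -0.5, nu, 1.2,
                                           normal_dist(0, 1))
      expect_gt(me, 0)
      expect_lt(me, nu)
      # no covariate effect restores collapsibility
      expect_equal(
        marginal_effect_by_integration(nm, -0.5, nu, 0, normal_dist(0, 1)),
        nu, tolerance = 1e-8)
    }
  }
})
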