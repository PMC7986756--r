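#' Characteristic collapsibility function
#'
#' For a link function f and a conditional treatment effect `nu` on the
#' linear-predictor scale, the characteristic collapsibility function (CCF)
#' maps the untreated outcome probability to the treated one:
#' g_nu(p) = f^{-1}\{f(p) + nu\}. Whether an effect measure is collapsible is
#' governed by the (non)linearity of this map: averaging over a covariate
#' distribution commutes with g_nu exactly when g_nu is linear (Jensen).
#'
#' For links that do not respect the unit interval (identity, log,
#' complementary-log) the result can fall outside (0,1); the value is still
#' returned, with a warning.
#'
#' @param link a `ccf_link` or link name (see [make_link()]).
#' @param nu conditional effect on the linear-predictor scale.
#' @param p untreated probability, in (0,1). Vectorized.
#' @return the treated probability g_nu(p).
#' @examples
#' ccf_eval("logit", log(10), 0.5) # 10*0.5/(1 + 9*0.5)
#' @export
ccf_eval <- function(link, nu, p) {
  link <- as_link(link)
  stopifnot(is.numeric(nu), length(nu) == 1L, is.finite(nu))
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("`p` must lie strictly inside (0,1)", call. = FALSE)
  out <- link$linkinv(link$linkfun(p) + nu)
  if (!link$respects_unit_interval && any(out <= 0 | out >= 1))
    warning(sprintf("CCF value outside (0,1) for the %s link", link$name),
            call. = FALSE)
  out
}

#' Classify a CCF as linear, concave or convex
#'
#' Samples g_nu on a grid of probabilities and inspects numerical second
#' differences. For the identity, log and complementary-log links the CCF is
#' affine and the classification is `"linear"` for every `nu`; for the
#' probability-respecting links it is concave for `nu > 0`, convex for
#' `nu < 0` and linear at `nu = 0`.
#'
#' @inheritParams ccf_eval
#' @param grid_n number of grid points in (0.001, 0.999).
#' @param tol tolerance on the scaled second differences.
#' @return one of `"linear"`, `"concave"`, `"convex"`.
#' @export
classify_ccf <- function(link, nu, grid_n = 512L, tol = 1e-8) {
  link <- as_link(link)
  stopifnot(is.finite(nu))
  p <- seq(0.001, 0.999, length.out = grid_n)
  g <- suppressWarnings(ccf_eval(link, nu, p))
  d2 <- diff(g, differences = 2L)
  scale <- max(abs(g)) + 1
  d2 <- d2 / scale
  if (all(abs(d2) <= tol)) return("linear")
  if (all(d2 <= tol)) return("concave")
  if (all(d2 >= -tol)) return("convex")
  stop("CCF is neither concave nor convex on (0,1); check the link",
       call. = FALSE)
}

#' Discrete-time rate model specification
#'
#' Describes a discrete-time survival process with `tau` intervals, a link on
#' the per-interval rate scale, a treatment effect `lam` on that scale, and
#' per-interval untreated rates. The default baseline is a constant
#' per-interval rate calibrated so the total untreated risk over all `tau`
#' intervals is 0.5.
#'
#' @param tau number of time intervals.
#' @param interval_index which interval l (1..tau) the CCF is evaluated for.
#' @param link rate-scale link (`ccf_link` or name).
#' @param lam treatment effect on the rate linear predictor.
#' @param baseline_rates optional vector of `tau` untreated per-interval
#'   rates in (0,1).
#' @return a list of class `rate_model_spec`.
#' @export
rate_model_spec <- function(tau, interval_index, link, lam,
                            baseline_rates = NULL) {
  stopifnot(tau >= 1, tau == as.integer(tau),
            interval_index >= 1, interval_index <= tau,
            is.finite(lam))
  link <- as_link(link)
  if (is.null(baseline_rates)) {
    # constant rate r with (1-r)^tau = 0.5
    baseline_rates <- rep(1 - 0.5^(1 / tau), tau)
  }
  if (length(baseline_rates) != tau ||
      any(baseline_rates <= 0 | baseline_rates >= 1))
    stop("`baseline_rates` must be `tau` values in (0,1)", call. = FALSE)
  structure(list(tau = as.integer(tau),
                 interval_index = as.integer(interval_index),
                 link = link, lam = lam,
                 baseline_rates = baseline_rates),
            class = "rate_model_spec")
}

#' CCF implied by a discrete-time rate model
#'
#' Rates condition on survival to the start of the interval, so the map from
#' the *unconditional* probability of an event in interval l under x = 0 to
#' the same probability under x = 1 is not simply a linear-predictor shift:
#' the treated and untreated survival through the preceding intervals differ.
#' This function (i) converts `p0` to the interval-l conditional rate using
#' the untreated survival through interval l-1, (ii) shifts all rates by
#' `lam` on the link scale, and (iii) reconverts using the treated survival.
#' For l = 1 it reduces exactly to [ccf_eval()]. As `tau` grows, the log-link
#' rate CCF converges to the cloglog-risk CCF (the proportional-hazards
#' limit).
#'
#' @param spec a [rate_model_spec()].
#' @param p0 unconditional probability of an event in interval l under x = 0,
#'   consistent with the baseline rates.
#' @return the unconditional probability of an event in interval l under
#'   x = 1.
#' @export
rate_ccf_eval <- function(spec, p0) {
  stopifnot(inherits(spec, "rate_model_spec"))
  if (any(p0 <= 0 | p0 >= 1))
    stop("`p0` must lie strictly inside (0,1)", call. = FALSE)
  l <- spec$interval_index
  r0 <- spec$baseline_rates
  s0_prev <- if (l > 1L) prod(1 - r0[seq_len(l - 1L)]) else 1
  r0_l <- p0 / s0_prev
  if (any(r0_l >= 1))
    stop(sprintf("implied untreated rate in interval %d is >= 1", l),
         call. = FALSE)
  shift <- function(r, j) {
    out <- spec$link$linkinv(spec$link$linkfun(r) + spec$lam)
    if (any(out <= 0 | out >= 1))
      stop(sprintf("implied treated rate outside (0,1) in interval %d", j),
           call. = FALSE)
    out
  }
  r1_prev <- if (l > 1L)
    vapply(seq_len(l - 1L), function(j) shift(r0[j], j), numeric(1))
  else numeric(0)
  r1_l <- shift(r0_l, l)
  r1_l * prod(1 - r1_prev)
}

#' Marginal effect by exact integration (the quadrature oracle)
#'
#' Computes the marginal effect on the link scale implied by the conditional
#' model f\{Pr(Y=1|X=x, C=c)\} = intercept + nu*x + covariate_coef*c, by
#' numerically integrating the conditional probabilities over the covariate
#' distribution for x = 1 and x = 0 and contrasting the averaged
#' probabilities on the link scale. For the logit link this is the marginal
#' log odds ratio. It serves as the independent oracle against which the
#' empirical standardization estimators are checked.
#'
#' @inheritParams ccf_eval
#' @param intercept,covariate_coef conditional model coefficients.
#' @param covariate_dist a [uniform_dist()] or [normal_dist()].
#' @param abs_tol absolute quadrature tolerance. Normal distributions are
#'   truncated at eight standard deviations.
#' @return the marginal log effect (scalar).
#' @examples
#' exp(marginal_effect_by_integration("logit", 0, log(10), 1,
#'                                    uniform_dist(-10, 10))) # about 1.6
#' @export
marginal_effect_by_integration <- function(link, intercept, nu,
                                           covariate_coef, covariate_dist,
                                           abs_tol = 1e-10) {
  link <- as_link(link)
  stopifnot(inherits(covariate_dist, "covariate_dist"),
            is.finite(intercept), is.finite(nu), is.finite(covariate_coef))
  if (covariate_dist$family == "uniform") {
    lower <- covariate_dist$min
    upper <- covariate_dist$max
    dens <- function(c) rep(1 / (upper - lower), length(c))
  } else {
    lower <- covariate_dist$mean - 8 * covariate_dist$sd
    upper <- covariate_dist$mean + 8 * covariate_dist$sd
    dens <- function(c) stats::dnorm(c, covariate_dist$mean,
                                     covariate_dist$sd)
  }
  avg_prob <- function(x) {
    f <- function(c) link$linkinv(intercept + nu * x + covariate_coef * c) *
      dens(c)
    q <- stats::integrate(f, lower, upper, abs.tol = abs_tol,
                          rel.tol = 1e-12, subdivisions = 500L)
    if (q$message != "OK")
      stop("quadrature did not converge: ", q$message, call. = FALSE)
    q$value
  }
  p1 <- avg_prob(1)
  p0 <- avg_prob(0)
  link$linkfun(p1) - link$linkfun(p0)
}
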