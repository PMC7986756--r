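#' Scenario specification for synthetic trials and cohorts
#'
#' Describes one data-generating mechanism. The four named study conditions
#' per outcome type are the coefficient pairs (0,1), (1,0) and (1,1) under
#' randomized exposure, and (1,1)* under observational (confounded) exposure
#' with Pr(X=1|C) = expit(C). A single standard-normal covariate C is drawn
#' once per study and held fixed across simulation replications.
#'
#' For the time-to-event outcome, subjects enter uniformly over a 2-year
#' recruitment window, the latent event time follows a conditional
#' proportional-hazards model with Weibull cumulative baseline hazard
#' H0(t) = scale * t^shape (scale 0.1, shape 1.5), and everyone still at risk
#' is administratively censored 10 years after the start of recruitment; the
#' analysis time-scale is time since recruitment.
#'
#' @param outcome `"binary"` or `"tte"`.
#' @param exposure `"rct"` (Pr(X=1) = 0.5) or `"observational"`
#'   (Pr(X=1|C) = expit(C)).
#' @param effect exposure coefficient (nu for binary, lambda for tte).
#' @param covariate_effect covariate coefficient (gamma / rho).
#' @param n subjects per dataset.
#' @param intercept binary-outcome model intercept mu.
#' @param weibull_scale,weibull_shape Weibull cumulative-hazard parameters.
#' @param recruitment_window length of the uniform entry window, years.
#' @param admin_end administrative censoring time, years since the start of
#'   the recruitment window.
#' @return a list of class `scenario_spec`.
#' @examples
#' scenario_spec("binary", "rct", effect = 1, covariate_effect = 1)
#' @export
scenario_spec <- function(outcome = c("binary", "tte"),
                          exposure = c("rct", "observational"),
                          effect, covariate_effect,
                          n = 1000L, intercept = 1,
                          weibull_scale = 0.1, weibull_shape = 1.5,
                          recruitment_window = 2, admin_end = 10) {
  outcome <- match.arg(outcome)
  exposure <- match.arg(exposure)
  stopifnot(is.finite(effect), is.finite(covariate_effect),
            n >= 1, weibull_scale > 0, weibull_shape > 0,
            recruitment_window >= 0, admin_end > recruitment_window)
  structure(list(outcome = outcome, exposure = exposure,
                 effect = effect, covariate_effect = covariate_effect,
                 n = as.integer(n), intercept = intercept,
                 weibull_scale = weibull_scale,
                 weibull_shape = weibull_shape,
                 recruitment_window = recruitment_window,
                 admin_end = admin_end),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> %s outcome, %s exposure, (%g,%g)%s, n=%d\n",
              x$outcome, x$exposure, x$effect, x$covariate_effect,
              if (x$exposure == "observational") "*" else "", x$n))
  invisible(x)
}

#' Simulate the fixed covariate vector
#'
#' Standard-normal covariate values, drawn once per study; the simulation
#' harness reuses the same vector across replications.
#'
#' @param n number of subjects.
#' @param seed integer seed.
#' @return numeric vector of length `n`.
#' @export
simulate_covariates <- function(n, seed) {
  stopifnot(n >= 1)
  set.seed(seed)
  stats::rnorm(n)
}

draw_exposure <- function(spec, covariates) {
  if (spec$exposure == "rct") stats::rbinom(length(covariates), 1L, 0.5)
  else stats::rbinom(length(covariates), 1L, stats::plogis(covariates))
}

#' Simulate a binary-outcome dataset
#'
#' Exposure is Bernoulli(0.5) (RCT) or Bernoulli(expit(C)) (observational);
#' the outcome follows the conditional logistic model
#' logit Pr(Y=1|X,C) = intercept + effect*X + covariate_effect*C.
#'
#' @param spec a [scenario_spec()] with `outcome = "binary"`.
#' @param covariates covariate vector of length `spec$n`
#'   (see [simulate_covariates()]).
#' @param seed integer seed for the exposure/outcome draws.
#' @return a `data.frame` with columns `outcome`, `exposure`, `c1`.
#' @export
simulate_binary <- function(spec, covariates, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"), spec$outcome == "binary",
            length(covariates) == spec$n)
  if (!is.null(seed)) set.seed(seed)
  x <- draw_exposure(spec, covariates)
  p <- stats::plogis(spec$intercept + spec$effect * x +
                       spec$covariate_effect * covariates)
  y <- stats::rbinom(spec$n, 1L, p)
  binary_data(outcome = y, exposure = x, covariates = covariates)
}

#' Simulate a right-censored time-to-event dataset
#'
#' The latent event time is drawn by inverse transform from the conditional
#' cumulative hazard H(t|X,C) = scale * t^shape * exp(effect*X +
#' covariate_effect*C). The censoring time is `admin_end` minus the uniform
#' entry time; observed time is the minimum of the two on the
#' time-since-recruitment scale.
#'
#' @param spec a [scenario_spec()] with `outcome = "tte"`.
#' @inheritParams simulate_binary
#' @return a `data.frame` with columns `time`, `event`, `exposure`, `c1`.
#' @export
simulate_tte <- function(spec, covariates, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"), spec$outcome == "tte",
            length(covariates) == spec$n)
  if (!is.null(seed)) set.seed(seed)
  x <- draw_exposure(spec, covariates)
  lp <- exp(spec$effect * x + spec$covariate_effect * covariates)
  # H(t) = scale * t^shape * lp; T = (E / (scale*lp))^(1/shape), E ~ Exp(1)
  e <- stats::rexp(spec$n)
  t_lat <- (e / (spec$weibull_scale * lp))^(1 / spec$weibull_shape)
  entry <- stats::runif(spec$n, 0, spec$recruitment_window)
  cens <- spec$admin_end - entry
  survival_data(time = pmin(t_lat, cens),
                event = as.integer(t_lat <= cens),
                exposure = x, covariates = covariates)
}

#' Simulate one dataset from a scenario
#'
#' Convenience dispatcher over [simulate_binary()] / [simulate_tte()].
#'
#' @inheritParams simulate_binary
#' @return a dataset `data.frame`.
#' @export
simulate_scenario <- function(spec, covariates, seed = NULL) {
  if (spec$outcome == "binary") simulate_binary(spec, covariates, seed)
  else simulate_tte(spec, covariates, seed)
}

#' The eight study conditions of the simulation design
#'
#' @param outcome `"binary"`, `"tte"`, or `"both"`.
#' @param n subjects per dataset.
#' @return named list of [scenario_spec()] objects; names like `"tte (1,1)*"`.
#' @export
standard_scenarios <- function(outcome = c("both", "binary", "tte"),
                               n = 1000L) {
  outcome <- match.arg(outcome)
  types <- if (outcome == "both") c("binary", "tte") else outcome
  out <- list()
  for (ty in types) {
    for (cf in list(c(0, 1), c(1, 0), c(1, 1))) {
      nm <- sprintf("%s (%g,%g)", ty, cf[1], cf[2])
      out[[nm]] <- scenario_spec(ty, "rct", cf[1], cf[2], n = n)
    }
    out[[sprintf("%s (1,1)*", ty)]] <-
      scenario_spec(ty, "observational", 1, 1, n = n)
  }
  out
}
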