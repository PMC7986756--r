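#' Configuration for the simulation-based marginal hazard ratio
#'
#' @param m simulated subjects per exposure arm (2m in total); increase `m`
#'   until repeated runs with different seeds agree to the precision at which
#'   results are quoted.
#' @param censoring how censoring is imposed on the simulated records:
#'   `"mimic"` (default) simulates censoring times from a flipped-indicator
#'   conditional Cox model standardized over the covariates, `"none"`
#'   censors only at the end of the event grid, `"admin_only"` draws
#'   censoring times from the covariate-free (Kaplan-Meier) censoring
#'   distribution, `"external_curves"` uses user-supplied censoring curves
#'   (`cens_curves`, a list with step curves `s0`, `s1` and their grid
#'   `times`).
#' @param time_frame restrict the marginalization to event times up to this
#'   value (default the full study length; longer is not possible without
#'   extrapolation). Survivors of the truncated grid are censored at its end.
#' @param seed integer seed; the event-arm and censoring-arm draws use
#'   independent substreams derived from it.
#' @param sampler `"inverse_transform"` (default; one uniform per subject) or
#'   `"bernoulli_chain"` (the literal interval-by-interval Bernoulli draws);
#'   the two are identical in distribution.
#' @param ties tie method for the Cox fits, including the final fit on the
#'   (heavily tied) simulated records.
#' @return a list of class `marginal_hr_config`.
#' @export
marginal_hr_config <- function(m = 5000L,
                               censoring = c("mimic", "none", "admin_only",
                                             "external_curves"),
                               time_frame = NULL, seed = 1L,
                               sampler = c("inverse_transform",
                                           "bernoulli_chain"),
                               ties = c("efron", "breslow"),
                               cens_curves = NULL) {
  censoring <- match.arg(censoring)
  sampler <- match.arg(sampler)
  ties <- match.arg(ties)
  stopifnot(m >= 1, is.null(time_frame) || time_frame > 0)
  if (censoring == "external_curves" && is.null(cens_curves))
    stop("censoring = 'external_curves' requires `cens_curves`",
         call. = FALSE)
  structure(list(m = as.integer(m), censoring = censoring,
                 time_frame = time_frame, seed = as.integer(seed),
                 sampler = sampler, ties = ties, cens_curves = cens_curves),
            class = "marginal_hr_config")
}

#' Draw survival times from a standardized curve on a discrete grid
#'
#' Simulates `m` subjects from the discrete-time process whose survival at
#' grid time t_l equals the curve value: the interval-l conditional survival
#' probability is S(t_l)/S(t_{l-1}); a subject's event time is the first
#' grid time whose interval Bernoulli fails, and subjects surviving all k
#' intervals are censored at the last grid time. The grid must contain
#' *event* times only. The inverse-transform sampler draws from the same
#' discrete distribution with a single uniform per subject.
#'
#' @param curve a survival [step_curve()] (or a numeric vector of survival
#'   values at `grid_times`).
#' @param grid_times strictly increasing event times t_1 < ... < t_k.
#' @param m number of simulated subjects.
#' @param seed integer seed.
#' @param sampler `"inverse_transform"` or `"bernoulli_chain"`.
#' @return a list with `time`, `event` (0/1), both length `m`.
#' @export
draw_times_from_curve <- function(curve, grid_times, m, seed,
                                  sampler = c("inverse_transform",
                                              "bernoulli_chain")) {
  sampler <- match.arg(sampler)
  if (is.unsorted(grid_times, strictly = TRUE) || any(grid_times <= 0))
    stop("`grid_times` must be strictly increasing and positive",
         call. = FALSE)
  s <- if (inherits(curve, "step_curve")) step_eval(curve, grid_times)
       else as.numeric(curve)
  if (length(s) != length(grid_times))
    stop("curve values and grid must have the same length", call. = FALSE)
  check_survival_curve(s)
  # clamp sub-tolerance numerical increases so the inversion below sees an
  # exactly nonincreasing curve
  s <- cummin(s)
  if (any(s[-length(s)] == 0))
    stop("survival reaches 0 before the end of the grid", call. = FALSE)
  k <- length(s)
  set.seed(seed)
  if (sampler == "inverse_transform") {
    u <- stats::runif(m)
    # count of grid survival values below u; since s is nonincreasing these
    # are the last n_below grid points, so the first failed interval is
    # k - n_below + 1 (no event when n_below = 0, i.e. u <= S(t_k))
    n_below <- findInterval(u, rev(s))
    first_fail <- k - n_below + 1L
    event <- as.integer(n_below > 0L)
    time <- ifelse(event == 1L, grid_times[pmin(first_fail, k)],
                   grid_times[k])
  } else {
    cond <- s / c(1, s[-k])
    alive <- rep(TRUE, m)
    time <- rep(grid_times[k], m)
    event <- integer(m)
    for (l in seq_len(k)) {
      idx <- which(alive)
      if (!length(idx)) break
      z <- stats::rbinom(length(idx), 1L, cond[l])
      died <- idx[z == 0L]
      if (length(died)) {
        time[died] <- grid_times[l]
        event[died] <- 1L
        alive[died] <- FALSE
      }
    }
  }
  list(time = time, event = event)
}

#' Conditional Cox model for the censoring mechanism
#'
#' Flips the event indicator (being censored becomes the event of interest;
#' subjects experiencing the original event are treated as censored) and fits
#' the conditional Cox model on exposure and covariates, with its Breslow
#' baseline. Justified by the independent-censoring assumption.
#'
#' @inheritParams fit_cox
#' @return a Cox `marg_fit` for the censoring process.
#' @export
fit_censoring_model <- function(data, ties = c("efron", "breslow")) {
  fit_cox(data, adjust = TRUE, ties = match.arg(ties), flip_event = TRUE)
}

#' Overlay simulated censoring times on simulated event times
#'
#' For each simulated subject the observed time is the earlier of the event
#' and censoring draws; the event indicator is 1 only when the event draw is
#' strictly earlier *and* was itself a true event (a subject whose "event"
#' was the grid-end censoring stays censored).
#'
#' @param event_arm,cens_arm lists as returned by [draw_times_from_curve()].
#' @return a list with `time` and `event`.
#' @export
overlay_censoring <- function(event_arm, cens_arm) {
  if (length(event_arm$time) != length(cens_arm$time))
    stop("event and censoring arms must have the same size", call. = FALSE)
  list(time = pmin(event_arm$time, cens_arm$time),
       event = as.integer(event_arm$time < cens_arm$time) * event_arm$event)
}

restrict_grid <- function(times, time_frame, allow_empty = FALSE) {
  if (is.null(time_frame)) return(times)
  out <- times[times <= time_frame]
  if (!length(out) && !allow_empty)
    stop("no grid times within the requested time frame", call. = FALSE)
  out
}

derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulation-based covariate-adjusted estimator of the marginal log hazard
#' ratio
#'
#' Marginalizes a conditional Cox fit to the marginal causal log hazard
#' ratio: (i) fit the conditional model on exposure and covariates; (ii)
#' standardize its survival curves over the empirical covariate distribution
#' for x = 0 and x = 1; (iii) simulate m subjects per arm from each
#' standardized curve on the observed event-time grid; (iv) under censoring
#' mimicry, repeat (i)-(iii) with event and censoring interchanged and
#' overlay the censoring draws; (v) fit a single-covariate Cox model to the
#' 2m stacked records. Its exposure coefficient is the estimate. Tied times
#' in the original data are broken by a seeded jitter many orders of
#' magnitude below the time resolution; ties among the simulated records are
#' expected and left to the tie method.
#'
#' The estimand is the marginal hazard ratio an RCT of the chosen time frame
#' would estimate; the standardized curves need not be proportional, so the
#' estimate is a censoring-and-time-frame-weighted average of a time-varying
#' marginal hazard ratio.
#'
#' @param data a [survival_data()] `data.frame`.
#' @param config a [marginal_hr_config()].
#' @param weights optional covariate-distribution weights passed to
#'   [standardized_survival()].
#' @return a [marg_estimate()] (method `"adjusted_marginal"`), with the
#'   conditional fit, standardized curves and settings in `meta`.
#' @export
marginal_log_hr <- function(data, config = marginal_hr_config(),
                            weights = NULL) {
  stopifnot(inherits(config, "marginal_hr_config"))
  d <- as.data.frame(data)
  seeds <- derive_seeds(config$seed, 3L)
  d$time <- jitter_tied_times(d$time, seeds[3L])
  max_t <- max(d$time)
  if (!is.null(config$time_frame) && config$time_frame > max_t)
    stop("`time_frame` exceeds the observed follow-up; extrapolation is ",
         "not supported", call. = FALSE)

  # step -1: conditional Cox fit; step 0: standardized survival curves
  fit <- fit_cox(d, adjust = TRUE, ties = config$ties)
  grid <- restrict_grid(sort(d$time[d$event == 1L]), config$time_frame)
  s0 <- standardized_survival(fit, d, 0, weights, times = grid)
  s1 <- standardized_survival(fit, d, 1, weights, times = grid)

  # steps 1-3 per arm
  arm0 <- draw_times_from_curve(s0, grid, config$m, seeds[1L],
                                config$sampler)
  arm1 <- draw_times_from_curve(s1, grid, config$m, seeds[1L] + 1L,
                                config$sampler)

  # an empty censoring grid (all censoring falls after the time frame) means
  # no censoring can occur within the frame, so the overlay is skipped
  cg <- restrict_grid(sort(d$time[d$event == 0L]), config$time_frame,
                      allow_empty = TRUE)
  if (config$censoring != "none" && length(cg)) {
    km_curve <- function() {
      km <- survival::survfit(survival::Surv(time, 1 - event) ~ 1, data = d)
      step_curve(cg, summary(km, times = cg, extend = TRUE)$surv,
                 value_before_first = 1)
    }
    if (config$censoring == "mimic") {
      cfit <- tryCatch(fit_censoring_model(d, ties = config$ties),
                       error = function(e) NULL)
      if (is.null(cfit)) {
        # too few censored subjects (or all in one arm) to support the
        # conditional censoring model: mimic the censoring distribution
        # marginally instead
        warning("censoring model inestimable; falling back to the ",
                "covariate-free Kaplan-Meier censoring distribution",
                call. = FALSE)
        sc0 <- sc1 <- km_curve()
      } else {
        sc0 <- standardized_survival(cfit, d, 0, weights, times = cg)
        sc1 <- standardized_survival(cfit, d, 1, weights, times = cg)
      }
    } else if (config$censoring == "admin_only") {
      sc0 <- sc1 <- km_curve()
    } else { # external_curves
      cg <- restrict_grid(config$cens_curves$times, config$time_frame)
      sc0 <- config$cens_curves$s0
      sc1 <- config$cens_curves$s1
    }
    cens0 <- draw_times_from_curve(sc0, cg, config$m, seeds[2L],
                                   config$sampler)
    cens1 <- draw_times_from_curve(sc1, cg, config$m, seeds[2L] + 1L,
                                   config$sampler)
    arm0 <- overlay_censoring(arm0, cens0)
    arm1 <- overlay_censoring(arm1, cens1)
  }

  sim_time <- c(arm0$time, arm1$time)
  sim_event <- c(arm0$event, arm1$event)
  sim_x <- rep(c(0L, 1L), each = config$m)
  if (sum(sim_event) < 1L)
    stop("no simulated events; increase `m` or check the curves",
         call. = FALSE)
  mfit <- survival::coxph(survival::Surv(sim_time, sim_event) ~ sim_x,
                          ties = config$ties)
  marg_estimate("log_hr_marginal", unname(stats::coef(mfit)),
                method = "adjusted_marginal",
                meta = list(m = config$m, seed = config$seed,
                            censoring = config$censoring,
                            sampler = config$sampler,
                            time_frame = config$time_frame,
                            conditional_fit = fit,
                            s0 = s0, s1 = s1,
                            sim_se = sqrt(diag(stats::vcov(mfit)))[1L],
                            n_sim_events = sum(sim_event)))
}
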