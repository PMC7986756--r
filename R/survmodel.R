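#' Fit the conditional logistic outcome model
#'
#' Maximum-likelihood logistic regression of the outcome on exposure and
#' (when `adjust = TRUE`) all covariate columns:
#' logit Pr(Y=1|X,C) = mu + nu*X + gamma'C. The unadjusted fit estimates the
#' marginal associational log odds ratio; the adjusted fit estimates the
#' conditional log odds ratio.
#'
#' @param data a [binary_data()] `data.frame`.
#' @param adjust include the covariate columns?
#' @return an object of class `marg_fit` with elements `kind` ("logistic"),
#'   `intercept`, `exposure_coef`, `covariate_coefs`, `n_subjects`,
#'   `n_events` (number of Y = 1), and the underlying `glm` as `model`.
#' @export
fit_logistic <- function(data, adjust = TRUE) {
  stopifnot(is.data.frame(data), all(c("outcome", "exposure") %in% names(data)))
  if (length(unique(data$outcome)) < 2L)
    stop("both outcome classes must be present", call. = FALSE)
  if (length(unique(data$exposure)) < 2L)
    stop("exposure is constant", call. = FALSE)
  cn <- if (adjust) covariate_names(data) else character(0)
  rhs <- paste(c("exposure", cn), collapse = " + ")
  fml <- stats::as.formula(paste("outcome ~", rhs))
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = data),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  if (any(abs(cf[-1L]) > 15)) {
    culprit <- names(which.max(abs(cf[-1L])))
    stop(sprintf("perfect (or quasi-perfect) separation detected for `%s`",
                 culprit), call. = FALSE)
  }
  structure(list(kind = "logistic",
                 intercept = unname(cf["(Intercept)"]),
                 exposure_coef = unname(cf["exposure"]),
                 covariate_coefs = cf[cn],
                 baseline_cumhaz = NULL,
                 n_subjects = nrow(data),
                 n_events = sum(data$outcome),
                 adjust = adjust,
                 model = fit),
            class = "marg_fit")
}

#' Fit the conditional Cox proportional hazards model
#'
#' Maximum partial-likelihood fit of
#' h(t|X,C) = h0(t) exp(lambda*X + rho'C) with the Breslow-type nonparametric
#' baseline cumulative hazard attached (see [breslow_baseline()]). The
#' unadjusted fit (`adjust = FALSE`) estimates the marginal associational log
#' hazard ratio.
#'
#' @param data a [survival_data()] `data.frame`.
#' @param adjust include the covariate columns?
#' @param ties tie handling for the partial likelihood: `"efron"` (default)
#'   or `"breslow"`.
#' @param flip_event fit the model for *censoring* instead: the event
#'   indicator is replaced by 1 - event (used by [fit_censoring_model()]).
#' @param baseline compute and attach the baseline cumulative hazard? Can be
#'   switched off when only coefficients are needed.
#' @return a `marg_fit` with `kind` "cox", `exposure_coef`,
#'   `covariate_coefs`, `baseline_cumhaz` (a [step_curve()]), `n_subjects`,
#'   `n_events`, and the `coxph` object as `model`.
#' @export
fit_cox <- function(data, adjust = TRUE, ties = c("efron", "breslow"),
                    flip_event = FALSE, baseline = TRUE) {
  ties <- match.arg(ties)
  stopifnot(is.data.frame(data),
            all(c("time", "event", "exposure") %in% names(data)))
  d <- as.data.frame(data)
  if (flip_event) d$event <- 1L - d$event
  if (sum(d$event) < 1L)
    stop(if (flip_event) "no censored subjects in the data"
         else "no events in the data", call. = FALSE)
  if (length(unique(d$exposure)) < 2L)
    stop("exposure is constant", call. = FALSE)
  cn <- if (adjust) covariate_names(d) else character(0)
  rhs <- paste(c("exposure", cn), collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  warn <- NULL
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = ties, x = FALSE, y = TRUE),
    warning = function(w) {
      warn <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  if (!is.null(warn) && grepl("infinite", warn))
    stop("monotone partial likelihood (a coefficient diverges): ", warn,
         call. = FALSE)
  if (anyNA(cf))
    stop("coefficient(s) inestimable (singular or degenerate design): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  out <- structure(list(kind = "cox",
                        intercept = NULL,
                        exposure_coef = unname(cf["exposure"]),
                        covariate_coefs = cf[cn],
                        baseline_cumhaz = NULL,
                        n_subjects = nrow(d),
                        n_events = sum(d$event),
                        ties = ties,
                        adjust = adjust,
                        model = fit),
                   class = "marg_fit")
  if (baseline) out$baseline_cumhaz <- breslow_baseline(out)
  out
}

#' @export
print.marg_fit <- function(x, ...) {
  cat(sprintf("<marg_fit> %s model, %d subjects, %d events\n", x$kind,
              x$n_subjects, x$n_events))
  cat(sprintf("  exposure coefficient: %.4f\n", x$exposure_coef))
  if (length(x$covariate_coefs))
    cat("  covariate coefficients:",
        paste(sprintf("%s=%.4f", names(x$covariate_coefs),
                      x$covariate_coefs), collapse = ", "), "\n")
  if (!is.null(x$intercept))
    cat(sprintf("  intercept: %.4f\n", x$intercept))
  invisible(x)
}

#' Breslow-type baseline cumulative hazard
#'
#' The nonparametric estimator of the cumulative baseline hazard of a fitted
#' Cox model (at covariates and exposure equal to zero), jumping at observed
#' event times; with `ties = "breslow"` the jump at an event time is the
#' number of events divided by the risk-set sum of exp(linear predictor),
#' with `"efron"` the matching Efron correction is used.
#'
#' @param fit a Cox `marg_fit`.
#' @return a nondecreasing [step_curve()] equal to 0 before the first event.
#' @export
breslow_baseline <- function(fit) {
  stopifnot(inherits(fit, "marg_fit"))
  if (fit$kind != "cox") stop("`fit` must be a Cox fit", call. = FALSE)
  bh <- survival::basehaz(fit$model, centered = FALSE)
  keep <- bh$time > 0
  step_curve(bh$time[keep], bh$hazard[keep], value_before_first = 0)
}

linear_predictor_risk <- function(fit, data, x) {
  cn <- names(fit$covariate_coefs)
  lp <- rep(fit$exposure_coef * x, nrow(data))
  if (length(cn))
    lp <- lp + as.matrix(data[cn]) %*% fit$covariate_coefs
  exp(drop(lp))
}

check_weights <- function(weights, n) {
  if (is.null(weights)) return(rep(1, n))
  if (length(weights) != n)
    stop("`weights` must have one entry per subject", call. = FALSE)
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("`weights` must be nonnegative and finite", call. = FALSE)
  if (sum(weights) == 0)
    stop("`weights` must not all be zero", call. = FALSE)
  weights
}

#' Standardized (covariate-averaged) survival curve
#'
#' The counterfactual survival curve under assignment to exposure `x`,
#' obtained by averaging the model-based subject-specific survival curves
#' exp\{-H0(t) exp(lambda*x + rho'C_i)\} over the empirical covariate
#' distribution of `data` (optionally reweighted, e.g. to marginalize over a
#' reference covariate distribution other than the study's).
#'
#' @param fit a Cox `marg_fit` with baseline cumulative hazard.
#' @param data dataset supplying the covariate distribution (typically the
#'   data the model was fitted to).
#' @param x exposure level, 0 or 1.
#' @param weights optional nonnegative subject weights (normalized
#'   internally); default the empirical distribution (equal weights).
#' @param times grid on which to evaluate; default the baseline's jump times.
#' @return a [step_curve()] starting at 1, nonincreasing.
#' @export
standardized_survival <- function(fit, data, x, weights = NULL,
                                  times = NULL) {
  stopifnot(inherits(fit, "marg_fit"))
  if (fit$kind != "cox" || is.null(fit$baseline_cumhaz))
    stop("`fit` must be a Cox fit with a baseline cumulative hazard",
         call. = FALSE)
  stopifnot(x %in% c(0, 1))
  w <- check_weights(weights, nrow(data))
  w <- w / sum(w)
  tms <- if (is.null(times)) fit$baseline_cumhaz$times else sort(unique(times))
  h0 <- step_eval(fit$baseline_cumhaz, tms)
  risk <- linear_predictor_risk(fit, data, x)
  s <- drop(crossprod(w, exp(-outer(risk, h0))))
  step_curve(tms, pmin(pmax(s, 0), 1), value_before_first = 1)
}

#' Complementary log-log parallelism diagnostic
#'
#' Plots of log(-log S_x(t)) for the two standardized curves are parallel
#' exactly when the marginal hazard ratio is constant in time; the returned
#' spread (maximum absolute deviation of the vertical gap from its mean)
#' quantifies departure from parallelism over the follow-up.
#'
#' @param s0,s1 standardized survival [step_curve()]s for x = 0 and x = 1.
#' @param trim evaluate only where both curves lie inside (trim, 1 - trim),
#'   avoiding the unstable extremes of the transform.
#' @return a list with `times`, `gap` (cloglog S1 - cloglog S0), `mean_gap`
#'   and `spread`.
#' @export
cloglog_parallelism <- function(s0, s1, trim = 0.02) {
  stopifnot(inherits(s0, "step_curve"), inherits(s1, "step_curve"))
  tms <- sort(unique(c(s0$times, s1$times)))
  v0 <- step_eval(s0, tms)
  v1 <- step_eval(s1, tms)
  ok <- v0 > trim & v0 < 1 - trim & v1 > trim & v1 < 1 - trim
  if (!any(ok))
    stop("no grid times with both curves inside the trimmed range",
         call. = FALSE)
  gap <- log(-log(v1[ok])) - log(-log(v0[ok]))
  list(times = tms[ok], gap = gap, mean_gap = mean(gap),
       spread = max(abs(gap - mean(gap))))
}

# Break tied times by a seeded uniform jitter of magnitude
# 1e-9 * (smallest positive gap); used to make the marginalization grids
# strictly increasing without materially moving any fit. The magnitude is
# floored at what double precision can resolve (relevant for bootstrap
# resamples, where distinct times can be arbitrarily close) and grown until
# no ties remain.
jitter_tied_times <- function(time, seed) {
  dup <- duplicated(time)
  if (!any(dup)) return(time)
  gaps <- diff(sort(unique(time)))
  eps <- if (length(gaps)) 1e-9 * min(gaps) else 1e-9 * min(time)
  eps <- max(eps,
             2 * (sum(dup) + 1) * max(abs(time)) * .Machine$double.eps)
  set.seed(seed)
  repeat {
    out <- time
    out[dup] <- out[dup] + stats::runif(sum(dup), 0, eps) + eps *
      seq_len(sum(dup)) / (sum(dup) + 1)
    if (!any(duplicated(out))) return(out)
    eps <- eps * 8
  }
}
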