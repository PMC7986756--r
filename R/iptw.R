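#' Propensity score model
#'
#' Logistic regression of exposure on the covariates; the inverse-probability
#' weights are 1/p-hat for the exposed and 1/(1 - p-hat) for the unexposed
#' (unstabilized by default).
#'
#' @param data a dataset with `exposure` and covariate columns.
#' @param stabilized multiply the weights by the marginal exposure
#'   probabilities (stabilized weights)?
#' @return a list of class `propensity_fit` with `coefficients`,
#'   `fitted` (strictly inside (0,1)) and `weights`.
#' @export
fit_propensity <- function(data, stabilized = FALSE) {
  stopifnot("exposure" %in% names(data))
  if (length(unique(data$exposure)) < 2L)
    stop("both exposure classes must be present", call. = FALSE)
  cn <- covariate_names(data)
  if (!length(cn)) stop("no covariates to model the propensity on",
                        call. = FALSE)
  fml <- stats::as.formula(paste("exposure ~", paste(cn, collapse = " + ")))
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = data),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (any(abs(stats::coef(fit)[-1L]) > 15))
    stop("perfect (or quasi-perfect) separation in the propensity model",
         call. = FALSE)
  p <- pmin(pmax(stats::fitted(fit), 1e-12), 1 - 1e-12)
  w <- ifelse(data$exposure == 1L, 1 / p, 1 / (1 - p))
  if (stabilized) {
    pbar <- mean(data$exposure)
    w <- w * ifelse(data$exposure == 1L, pbar, 1 - pbar)
  }
  structure(list(coefficients = stats::coef(fit), fitted = p, weights = w,
                 stabilized = stabilized),
            class = "propensity_fit")
}

check_iptw_weights <- function(w, cap) {
  wn <- w / sum(w)
  if (max(wn) > cap)
    warning(sprintf(
      "extreme IPT weights: max normalized weight %.3g exceeds cap %.3g (%d subjects above cap)",
      max(wn), cap, sum(wn > cap)), call. = FALSE)
  invisible(wn)
}

#' Inverse-probability-of-treatment-weighted estimators
#'
#' The unadjusted model refitted with inverse probability of treatment
#' weights, estimating the marginal causal log odds ratio
#' (`iptw_log_or`, weighted logistic regression of outcome on exposure) or
#' the marginal causal log hazard ratio (`iptw_log_hr`, weighted unadjusted
#' Cox partial likelihood). Standard errors should come from the shared
#' bootstrap, which re-fits the propensity model in every resample.
#'
#' @param data a [binary_data()] / [survival_data()] `data.frame`.
#' @param weights optional externally supplied weights (skips the propensity
#'   fit; with equal weights the estimators reduce to the unadjusted ones).
#' @param stabilized passed to [fit_propensity()].
#' @param weight_cap warn when the maximum normalized weight exceeds this.
#' @param ties tie method for the weighted Cox fit.
#' @return a [marg_estimate()] with method `"iptw"`.
#' @export
iptw_log_or <- function(data, weights = NULL, stabilized = FALSE,
                        weight_cap = 0.05) {
  w <- if (is.null(weights)) fit_propensity(data, stabilized)$weights
       else check_weights(weights, nrow(data))
  check_iptw_weights(w, weight_cap)
  d <- as.data.frame(data)
  d$.w <- w
  fit <- stats::glm(outcome ~ exposure, family = stats::quasibinomial(),
                    data = d, weights = .w)
  marg_estimate("log_or_marginal", unname(stats::coef(fit)["exposure"]),
                method = "iptw", meta = list(stabilized = stabilized))
}

#' @rdname iptw_log_or
#' @export
iptw_log_hr <- function(data, weights = NULL, stabilized = FALSE,
                        weight_cap = 0.05, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  w <- if (is.null(weights)) fit_propensity(data, stabilized)$weights
       else check_weights(weights, nrow(data))
  check_iptw_weights(w, weight_cap)
  d <- as.data.frame(data)
  d$.w <- w
  fit <- survival::coxph(survival::Surv(time, event) ~ exposure,
                         data = d, weights = .w, ties = ties)
  marg_estimate("log_hr_marginal", unname(stats::coef(fit)["exposure"]),
                method = "iptw", meta = list(stabilized = stabilized))
}
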