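#' Effect estimate container
#'
#' A point estimate of a log odds-ratio or log hazard-ratio estimand,
#' optionally with a bootstrap standard error and percentile confidence
#' interval (see [np_bootstrap()] and [with_bootstrap()]).
#'
#' @param estimand one of `"log_or_marginal"`, `"log_or_conditional"`,
#'   `"log_hr_marginal"`, `"log_hr_conditional"`.
#' @param estimate point estimate.
#' @param method one of `"unadjusted"`, `"iptw"`, `"adjusted_marginal"`,
#'   `"conditional"`.
#' @param se,ci_low,ci_high optional bootstrap inference.
#' @param meta named list of provenance (m, B, seeds, ...).
#' @return an object of class `marg_estimate`.
#' @export
marg_estimate <- function(estimand, estimate, method, se = NULL,
                          ci_low = NULL, ci_high = NULL, meta = list()) {
  estimand <- match.arg(estimand, c("log_or_marginal", "log_or_conditional",
                                    "log_hr_marginal", "log_hr_conditional"))
  method <- match.arg(method, c("unadjusted", "iptw", "adjusted_marginal",
                                "conditional"))
  stopifnot(is.numeric(estimate), length(estimate) == 1L)
  if (!is.null(ci_low) && !is.null(ci_high) &&
      (ci_low > estimate || ci_high < estimate))
    warning("percentile CI does not bracket the point estimate ",
            "(possible under extreme skew)", call. = FALSE)
  structure(list(estimand = estimand, estimate = estimate, method = method,
                 se = se, ci_low = ci_low, ci_high = ci_high, meta = meta),
            class = "marg_estimate")
}

#' @export
print.marg_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("<marg_estimate> %s (%s method)\n", x$estimand, x$method))
  cat("  estimate:", format(round(x$estimate, digits)), "\n")
  if (!is.null(x$se))
    cat("  bootstrap SE:", format(round(x$se, digits)), "\n")
  if (!is.null(x$ci_low))
    cat(sprintf("  95%% percentile CI: [%s, %s]\n",
                format(round(x$ci_low, digits)),
                format(round(x$ci_high, digits))))
  invisible(x)
}

#' @export
as.double.marg_estimate <- function(x, ...) x$estimate
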