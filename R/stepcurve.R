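#' Right-continuous step functions
#'
#' Container for cumulative baseline hazards and standardized survival
#' curves: a right-continuous piecewise-constant function on [0, max(times)]
#' with jumps at `times`.
#'
#' @param times strictly increasing positive jump times.
#' @param values function values at (and after) each jump time.
#' @param value_before_first value on [0, times[1]); 0 for cumulative
#'   hazards, 1 for survival curves.
#' @return an object of class `step_curve`.
#' @export
step_curve <- function(times, values, value_before_first) {
  stopifnot(length(times) == length(values), length(times) >= 1L)
  if (any(!is.finite(times)) || any(times <= 0) ||
      is.unsorted(times, strictly = TRUE))
    stop("`times` must be strictly increasing and positive", call. = FALSE)
  if (any(!is.finite(values)))
    stop("`values` must be finite", call. = FALSE)
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 value_before_first = value_before_first),
            class = "step_curve")
}

#' Evaluate a step curve
#'
#' @param curve a [step_curve()].
#' @param t evaluation times (vectorized); values beyond the last jump time
#'   carry the last value forward.
#' @return numeric vector.
#' @export
step_eval <- function(curve, t) {
  stopifnot(inherits(curve, "step_curve"))
  idx <- findInterval(t, curve$times)
  c(curve$value_before_first, curve$values)[idx + 1L]
}

#' @export
print.step_curve <- function(x, ...) {
  k <- length(x$times)
  cat(sprintf(
    "<step_curve> %d jumps on (%g, %g]; value before first: %g, last: %g\n",
    k, min(x$times), max(x$times), x$value_before_first, x$values[k]))
  invisible(x)
}

#' @export
as.data.frame.step_curve <- function(x, ...) {
  data.frame(time = x$times, value = x$values)
}

# survival-type curve sanity used by the simulation sampler
check_survival_curve <- function(values, value_before_first = 1) {
  v <- c(value_before_first, values)
  if (any(diff(v) > 1e-12))
    stop("survival curve must be nonincreasing on the grid", call. = FALSE)
  if (any(values < 0) || any(values > 1))
    stop("survival curve must lie in [0,1]", call. = FALSE)
  invisible(TRUE)
}
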