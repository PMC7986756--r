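#' Nonparametric bootstrap for any estimator
#'
#' Resamples subjects (rows) with replacement and re-runs the full estimation
#' procedure on each resample — for the simulation-based hazard-ratio
#' estimator this re-fits both conditional Cox models and redoes the internal
#' simulation with a fresh substream. Standard error is the standard
#' deviation of the replicate estimates; the 95% confidence interval is the
#' 2.5th/97.5th percentile interval. Replicates that error (e.g. separation
#' in a resample) are dropped and counted, with a warning when more than 5%
#' fail.
#'
#' @param data a dataset `data.frame`; the resampling unit is the row.
#' @param statistic `function(data, seed)` returning a numeric scalar (or a
#'   [marg_estimate()]); the per-replicate `seed` is derived deterministically
#'   from `seed` so that runs are reproducible and order-independent.
#' @param B number of bootstrap resamples (at least 2).
#' @param seed master integer seed.
#' @param stratify_by optional column name; resampling is then done within
#'   the levels of that column (e.g. `"exposure"`).
#' @param conf confidence level for the percentile interval.
#' @return an object of class `boot_result`: `replicates`, `se`, `ci_low`,
#'   `ci_high`, `n_failed`.
#' @export
np_bootstrap <- function(data, statistic, B = 1000L, seed = 1L,
                         stratify_by = NULL, conf = 0.95) {
  stopifnot(B >= 2, is.function(statistic))
  n <- nrow(data)
  strata <- if (is.null(stratify_by)) rep(1L, n)
            else as.integer(factor(data[[stratify_by]]))
  groups <- split(seq_len(n), strata)
  est <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    rep_seed <- (seed + 104729L * b) %% .Machine$integer.max
    set.seed(rep_seed)
    idx <- unlist(lapply(groups, function(g)
      g[sample.int(length(g), replace = TRUE)]), use.names = FALSE)
    val <- tryCatch(statistic(data[idx, , drop = FALSE], rep_seed),
                    error = function(e) NA_real_)
    if (inherits(val, "marg_estimate")) val <- val$estimate
    est[b] <- val
  }
  ok <- est[is.finite(est)]
  n_failed <- B - length(ok)
  if (length(ok) == 0L)
    stop("all bootstrap replicates failed", call. = FALSE)
  if (n_failed > 0.05 * B)
    warning(sprintf("%d of %d bootstrap replicates failed", n_failed, B),
            call. = FALSE)
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(ok, c(alpha, 1 - alpha), type = 7))
  structure(list(replicates = ok, se = stats::sd(ok),
                 ci_low = ci[1L], ci_high = ci[2L],
                 n_failed = n_failed, B = B, seed = seed),
            class = "boot_result")
}

#' @export
print.boot_result <- function(x, digits = 4, ...) {
  cat(sprintf("<boot_result> B = %d (%d failed)\n", x$B, x$n_failed))
  cat(sprintf("  SE: %s;  95%% percentile CI: [%s, %s]\n",
              format(round(x$se, digits)), format(round(x$ci_low, digits)),
              format(round(x$ci_high, digits))))
  invisible(x)
}

#' Attach bootstrap inference to an estimate
#'
#' Convenience wrapper: runs [np_bootstrap()] of `statistic` on `data` and
#' copies the SE and percentile CI into the [marg_estimate()].
#'
#' @param est a [marg_estimate()] (the point estimate on the full data).
#' @inheritParams np_bootstrap
#' @return the estimate with `se`, `ci_low`, `ci_high` and bootstrap metadata
#'   filled in.
#' @export
with_bootstrap <- function(est, data, statistic, B = 1000L, seed = 1L,
                           stratify_by = NULL) {
  stopifnot(inherits(est, "marg_estimate"))
  bt <- np_bootstrap(data, statistic, B = B, seed = seed,
                     stratify_by = stratify_by)
  marg_estimate(est$estimand, est$estimate, est$method,
                se = bt$se, ci_low = bt$ci_low, ci_high = bt$ci_high,
                meta = c(est$meta, list(B = bt$B, boot_seed = seed,
                                        boot_failed = bt$n_failed)))
}
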