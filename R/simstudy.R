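#' Monte Carlo performance measures
#'
#' Sample mean and empirical standard error of a set of replicate estimates,
#' with their Monte Carlo standard errors: SE(mean) = empSE/sqrt(n_sim) and
#' SE(empSE) = empSE/sqrt(2(n_sim - 1)).
#'
#' @param estimates numeric vector of replicate estimates (length >= 2).
#' @return a named list: `mean`, `mean_mc_error`, `emp_se`,
#'   `emp_se_mc_error`, `n_sim`.
#' @export
mc_errors <- function(estimates) {
  estimates <- estimates[is.finite(estimates)]
  n <- length(estimates)
  if (n < 2L) stop("need at least two estimates", call. = FALSE)
  emp_se <- stats::sd(estimates)
  list(mean = mean(estimates),
       mean_mc_error = emp_se / sqrt(n),
       emp_se = emp_se,
       emp_se_mc_error = emp_se / sqrt(2 * (n - 1)),
       n_sim = n)
}

#' Apply one comparison method to one dataset
#'
#' The four analysis methods of the study design: (A) unadjusted logistic or
#' Cox model, (B) the unadjusted model with inverse probability of treatment
#' weighting, (C) the standardization estimator of the marginal effect
#' ([marginal_log_or()] for binary outcomes, [marginal_log_hr()] for
#' time-to-event), (D) the adjusted (conditional) model.
#'
#' @param data a [binary_data()] or [survival_data()] `data.frame`.
#' @param method `"unadjusted"`, `"iptw"`, `"adjusted_marginal"` or
#'   `"conditional"`.
#' @param hr_config [marginal_hr_config()] used when `method =
#'   "adjusted_marginal"` on survival data.
#' @return the estimate (numeric scalar, log OR or log HR).
#' @export
apply_method <- function(data, method = c("unadjusted", "iptw",
                                          "adjusted_marginal",
                                          "conditional"),
                         hr_config = marginal_hr_config()) {
  method <- match.arg(method)
  if (inherits(data, "binary_data") || "outcome" %in% names(data)) {
    switch(method,
      unadjusted = fit_logistic(data, adjust = FALSE)$exposure_coef,
      iptw = iptw_log_or(data)$estimate,
      adjusted_marginal =
        marginal_log_or(fit_logistic(data, adjust = TRUE), data)$estimate,
      conditional = fit_logistic(data, adjust = TRUE)$exposure_coef)
  } else {
    switch(method,
      unadjusted = fit_cox(data, adjust = FALSE, baseline = FALSE)$exposure_coef,
      iptw = iptw_log_hr(data)$estimate,
      adjusted_marginal = marginal_log_hr(data, hr_config)$estimate,
      conditional = fit_cox(data, adjust = TRUE, baseline = FALSE)$exposure_coef)
  }
}

#' Run one simulation scenario
#'
#' Simulates `n_sim` datasets from a [scenario_spec()] (the covariate vector
#' is drawn once from `base_seed` and shared across replications), applies
#' each requested method, and summarizes each method's replicate estimates
#' with [mc_errors()]. Replication r uses seed `base_seed + r`; the internal
#' simulation of the hazard-ratio marginalization uses a further substream.
#' Failed replications are counted per method, not fatal.
#'
#' @param spec a [scenario_spec()].
#' @param methods subset of the four method names.
#' @param n_sim number of simulated datasets.
#' @param base_seed integer seed.
#' @param hr_config template [marginal_hr_config()] for the
#'   `adjusted_marginal` method on survival data (its seed is replaced per
#'   replication).
#' @param checkpoint optional CSV path; per-replication estimates are
#'   appended there and an interrupted run resumes from it.
#' @param label scenario label used in the summary.
#' @return a `data.frame` with one row per method: `scenario`, `method`,
#'   `mean`, `mean_mc_error`, `emp_se`, `emp_se_mc_error`, `n_sim`,
#'   `n_failed`; the raw estimates matrix is attached as attribute
#'   `"estimates"`.
#' @export
run_scenario <- function(spec, methods = c("unadjusted", "iptw",
                                           "adjusted_marginal",
                                           "conditional"),
                         n_sim = 1000L, base_seed = 1L,
                         hr_config = marginal_hr_config(),
                         checkpoint = NULL, label = NULL) {
  methods <- match.arg(methods, several.ok = TRUE,
                       choices = c("unadjusted", "iptw", "adjusted_marginal",
                                   "conditional"))
  if (is.null(label))
    label <- sprintf("%s (%g,%g)%s", spec$outcome, spec$effect,
                     spec$covariate_effect,
                     if (spec$exposure == "observational") "*" else "")
  covariates <- simulate_covariates(spec$n, base_seed)
  est <- matrix(NA_real_, n_sim, length(methods),
                dimnames = list(NULL, methods))
  start <- 1L
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    prev <- utils::read.csv(checkpoint)
    done <- min(nrow(prev), n_sim)
    if (done > 0L) {
      est[seq_len(done), ] <- as.matrix(prev[seq_len(done), methods,
                                             drop = FALSE])
      start <- done + 1L
    }
  }
  for (r in seq(from = start, length.out = max(0L, n_sim - start + 1L))) {
    rep_seed <- (base_seed + r) %% .Machine$integer.max
    data <- simulate_scenario(spec, covariates, seed = rep_seed)
    cfg <- hr_config
    cfg$seed <- (rep_seed + 500003L) %% .Machine$integer.max
    for (mth in methods) {
      est[r, mth] <- tryCatch(
        suppressWarnings(apply_method(data, mth, hr_config = cfg)),
        error = function(e) NA_real_)
    }
    if (!is.null(checkpoint))
      utils::write.csv(as.data.frame(est[seq_len(r), , drop = FALSE]),
                       checkpoint, row.names = FALSE)
  }
  out <- do.call(rbind, lapply(methods, function(mth) {
    s <- mc_errors(est[, mth])
    data.frame(scenario = label, method = mth, mean = s$mean,
               mean_mc_error = s$mean_mc_error, emp_se = s$emp_se,
               emp_se_mc_error = s$emp_se_mc_error, n_sim = s$n_sim,
               n_failed = n_sim - s$n_sim)
  }))
  attr(out, "estimates") <- est
  out
}

#' Full simulation-study grid
#'
#' Runs all eight study conditions (four binary, four time-to-event) under
#' the four methods, with the simulation-based marginal hazard-ratio
#' estimator repeated for each per-arm size in `m_values`. Output is a long
#' table of performance summaries mirroring the study design's layout
#' (render with [format_table1()]).
#'
#' @param n_sim replications per scenario.
#' @param base_seed integer seed (each scenario gets an offset substream).
#' @param m_values per-arm simulation sizes for the marginal HR estimator
#'   (2m per value in the labels).
#' @param outcome `"both"`, `"binary"` or `"tte"`.
#' @param n subjects per simulated dataset.
#' @param hr_censoring censoring mode for the marginal HR estimator.
#' @param checkpoint_dir optional directory for per-scenario checkpoints.
#' @return a long `data.frame` of performance summaries with an `m` column
#'   (NA except for the simulation-based estimator).
#' @export
reproduce_table1 <- function(n_sim = 1000L, base_seed = 1L,
                             m_values = c(500L, 2500L, 5000L),
                             outcome = c("both", "binary", "tte"),
                             n = 1000L, hr_censoring = "mimic",
                             checkpoint_dir = NULL) {
  outcome <- match.arg(outcome)
  scen <- standard_scenarios(outcome, n = n)
  rows <- list()
  for (i in seq_along(scen)) {
    spec <- scen[[i]]
    label <- names(scen)[i]
    seed_i <- (base_seed + 7919L * i) %% .Machine$integer.max
    ckpt <- function(tag) if (is.null(checkpoint_dir)) NULL else
      file.path(checkpoint_dir, paste0(gsub("[^a-z0-9]+", "_", label), "_",
                                       tag, ".csv"))
    if (spec$outcome == "binary") {
      r <- run_scenario(spec, n_sim = n_sim, base_seed = seed_i,
                        checkpoint = ckpt("all"), label = label)
      r$m <- NA_integer_
      rows[[length(rows) + 1L]] <- r
    } else {
      r <- run_scenario(spec, methods = c("unadjusted", "iptw",
                                          "conditional"),
                        n_sim = n_sim, base_seed = seed_i,
                        checkpoint = ckpt("basic"), label = label)
      r$m <- NA_integer_
      rows[[length(rows) + 1L]] <- r
      for (m in m_values) {
        cfg <- marginal_hr_config(m = m, censoring = hr_censoring)
        rm_ <- run_scenario(spec, methods = "adjusted_marginal",
                            n_sim = n_sim, base_seed = seed_i,
                            hr_config = cfg,
                            checkpoint = ckpt(paste0("m", m)), label = label)
        rm_$m <- as.integer(m)
        rows[[length(rows) + 1L]] <- rm_
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a simulation-study summary as fixed-width text
#'
#' @param tab output of [reproduce_table1()] or [run_scenario()].
#' @return character vector of lines (invisibly printed).
#' @export
format_table1 <- function(tab) {
  if (is.null(tab$m)) tab$m <- NA_integer_
  lines <- sprintf(
    "%-16s %-18s %-9s mean %6.2f (%.4f)   empSE %5.2f (%.4f)  [n_sim %d]",
    tab$scenario, tab$method,
    ifelse(is.na(tab$m), "", sprintf("2m=%d", 2L * tab$m)),
    tab$mean, tab$mean_mc_error, tab$emp_se, tab$emp_se_mc_error, tab$n_sim)
  cat(lines, sep = "\n")
  invisible(lines)
}
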