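# Shared fixtures, built in code.

# Small survival dataset with known structure and no ties.
toy_survival <- function() {
  survival_data(
    time = c(1, 2, 3, 4, 5, 6, 7, 8),
    event = c(1, 1, 0, 1, 1, 0, 1, 1),
    exposure = c(1, 0, 1, 0, 1, 1, 0, 0),
    covariates = c(0.5, -0.2, 0.1, 0.8, -0.5, 0.0, 0.3, -0.7)
  )
}

# Brute-force maximizer of the Breslow log partial likelihood for a single
# binary covariate, used as an independent oracle for fit_cox.
grid_cox_coef <- function(time, event, x, lo = -5, hi = 5, step = 1e-4) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  betas <- seq(lo, hi, by = step)
  ll <- vapply(betas, function(b) {
    lp <- b * x
    s <- 0
    for (i in which(event == 1L)) {
      risk <- time >= time[i]
      s <- s + lp[i] - log(sum(exp(lp[risk])))
    }
    s
  }, numeric(1))
  betas[which.max(ll)]
}

# Closed-form Weibull survival used by the generators: S(t) = exp(-0.1 t^1.5).
weibull_surv <- function(t) exp(-0.1 * t^1.5)

expit <- stats::plogis
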