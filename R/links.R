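#' Link functions for binary-outcome and rate models
#'
#' Constructs a link object mapping probabilities (or per-interval rates) to
#' the scale of the linear predictor and back. The available links are
#' \describe{
#'   \item{identity}{f(p) = p (risk differences)}
#'   \item{log}{f(p) = log p (risk ratios)}
#'   \item{logit}{f(p) = log\{p/(1-p)\} (odds ratios)}
#'   \item{cloglog}{f(p) = log\{-log(1-p)\} (the risk link implied by
#'     proportional hazards)}
#'   \item{probit}{f(p) = qnorm(p)}
#'   \item{complementary-log}{f(p) = log(1-p) (the risk link implied by
#'     additive hazards; its collapsibility function is affine)}
#' }
#' The identity, log and complementary-log links are not
#' "probability-respecting": shifting on the linear-predictor scale can leave
#' the interval (0,1).
#'
#' @param name one of `"identity"`, `"log"`, `"logit"`, `"cloglog"`,
#'   `"probit"`, `"complementary-log"`.
#' @return an object of class `ccf_link` with elements `name`, `linkfun`
#'   (probability to linear predictor), `linkinv` (back-transform) and
#'   `respects_unit_interval` (logical).
#' @examples
#' l <- make_link("logit")
#' l$linkinv(l$linkfun(0.3)) # 0.3
#' @export
make_link <- function(name = c("identity", "log", "logit", "cloglog",
                               "probit", "complementary-log")) {
  name <- match.arg(name)
  l <- switch(name,
    identity = list(
      linkfun = function(p) p,
      linkinv = function(z) z,
      respects_unit_interval = FALSE),
    log = list(
      linkfun = function(p) log(p),
      linkinv = function(z) exp(z),
      respects_unit_interval = FALSE),
    logit = list(
      linkfun = function(p) stats::qlogis(p),
      linkinv = function(z) stats::plogis(z),
      respects_unit_interval = TRUE),
    cloglog = list(
      linkfun = function(p) log(-log1p(-p)),
      linkinv = function(z) -expm1(-exp(z)),
      respects_unit_interval = TRUE),
    probit = list(
      linkfun = function(p) stats::qnorm(p),
      linkinv = function(z) stats::pnorm(z),
      respects_unit_interval = TRUE),
    `complementary-log` = list(
      linkfun = function(p) log1p(-p),
      linkinv = function(z) -expm1(z),
      respects_unit_interval = FALSE)
  )
  l$name <- name
  class(l) <- "ccf_link"
  l
}

#' @export
print.ccf_link <- function(x, ...) {
  cat("<ccf_link> ", x$name,
      if (!x$respects_unit_interval) " (does not respect [0,1])", "\n",
      sep = "")
  invisible(x)
}

as_link <- function(link) {
  if (inherits(link, "ccf_link")) return(link)
  if (is.character(link) && length(link) == 1L) return(make_link(link))
  stop("`link` must be a ccf_link object or a link name", call. = FALSE)
}

#' Covariate distribution specifications
#'
#' Small helpers describing the distribution of a scalar covariate, used by
#' [marginal_effect_by_integration()] as the integration measure.
#'
#' @param min,max bounds of the uniform distribution.
#' @param mean,sd mean and standard deviation of the normal distribution.
#' @return a list of class `covariate_dist`.
#' @export
uniform_dist <- function(min, max) {
  stopifnot(is.finite(min), is.finite(max), max > min)
  structure(list(family = "uniform", min = min, max = max),
            class = "covariate_dist")
}

#' @rdname uniform_dist
#' @export
normal_dist <- function(mean = 0, sd = 1) {
  stopifnot(is.finite(mean), is.finite(sd), sd > 0)
  structure(list(family = "normal", mean = mean, sd = sd),
            class = "covariate_dist")
}
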