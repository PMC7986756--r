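#' Subject-level datasets
#'
#' Light validated containers for the two dataset types. Both are plain
#' `data.frame`s with reserved column names; every other column is treated as
#' a covariate by the fitting functions. `binary_data` holds a binary outcome
#' study (`outcome`, `exposure`, covariates); `survival_data` holds a
#' right-censored time-to-event study (`time`, `event`, `exposure`,
#' covariates).
#'
#' @param outcome 0/1 outcome vector.
#' @param time positive follow-up times.
#' @param event 0/1 event indicator (1 = event, 0 = censored).
#' @param exposure 0/1 exposure vector.
#' @param covariates numeric vector or matrix/data.frame of covariates;
#'   unnamed columns are named `c1`, `c2`, ...
#' @return a `data.frame` (class `binary_data` / `survival_data`).
#' @export
binary_data <- function(outcome, exposure, covariates = NULL) {
  check_binary(outcome, "outcome")
  check_binary(exposure, "exposure")
  stopifnot(length(outcome) == length(exposure))
  d <- data.frame(outcome = as.integer(outcome),
                  exposure = as.integer(exposure))
  d <- bind_covariates(d, covariates)
  class(d) <- c("binary_data", "data.frame")
  d
}

#' @rdname binary_data
#' @export
survival_data <- function(time, event, exposure, covariates = NULL) {
  if (any(!is.finite(time)) || any(time <= 0))
    stop("`time` must be positive and finite", call. = FALSE)
  check_binary(event, "event")
  check_binary(exposure, "exposure")
  stopifnot(length(time) == length(event), length(time) == length(exposure))
  d <- data.frame(time = as.numeric(time), event = as.integer(event),
                  exposure = as.integer(exposure))
  d <- bind_covariates(d, covariates)
  class(d) <- c("survival_data", "data.frame")
  d
}

check_binary <- function(x, what) {
  if (length(x) == 0L || anyNA(x) || !all(x %in% c(0, 1)))
    stop(sprintf("`%s` must be 0/1 with no missing values", what),
         call. = FALSE)
  invisible(TRUE)
}

bind_covariates <- function(d, covariates) {
  if (is.null(covariates)) return(d)
  if (is.atomic(covariates) && is.null(dim(covariates)))
    covariates <- data.frame(c1 = covariates)
  cv <- as.data.frame(covariates)
  if (nrow(cv) != nrow(d))
    stop("covariates must have one row per subject", call. = FALSE)
  if (anyNA(cv)) stop("covariates must not contain missing values",
                      call. = FALSE)
  anon <- is.na(names(cv)) | names(cv) == "" | grepl("^V[0-9]+$", names(cv))
  names(cv)[anon] <- paste0("c", which(anon))
  cbind(d, cv)
}

reserved_cols <- c("outcome", "time", "event", "exposure")

#' Names of the covariate columns of a dataset
#' @param data a dataset `data.frame`.
#' @return character vector (possibly empty).
#' @export
covariate_names <- function(data) {
  setdiff(names(data), reserved_cols)
}

covariate_matrix <- function(data) {
  cn <- covariate_names(data)
  if (length(cn) == 0L) return(matrix(0, nrow(data), 0L))
  as.matrix(data[cn])
}

#' Read subject-level datasets from delimited text
#'
#' @param path CSV file path.
#' @param outcome,time,event,exposure column names in the file.
#' @param covariates character vector of covariate column names; default all
#'   remaining columns.
#' @return a [binary_data()] / [survival_data()] object.
#' @export
read_binary_data <- function(path, outcome = "outcome",
                             exposure = "exposure", covariates = NULL) {
  raw <- utils::read.csv(path)
  if (is.null(covariates))
    covariates <- setdiff(names(raw), c(outcome, exposure))
  binary_data(raw[[outcome]], raw[[exposure]],
              if (length(covariates)) raw[covariates])
}

#' @rdname read_binary_data
#' @export
read_survival_data <- function(path, time = "time", event = "event",
                               exposure = "exposure", covariates = NULL) {
  raw <- utils::read.csv(path)
  if (is.null(covariates))
    covariates <- setdiff(names(raw), c(time, event, exposure))
  survival_data(raw[[time]], raw[[event]], raw[[exposure]],
                if (length(covariates)) raw[covariates])
}
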