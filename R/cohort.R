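#' Validate and standardize a recalibration cohort
#'
#' A cohort is a data frame with one row per subject, a binary outcome column
#' `y` (1 = case, i.e. the subject experiences the event without intervention;
#' 0 = control) and a predicted-risk column `s` strictly inside (0, 1).
#' Extra columns are kept but ignored by all estimators. Risks exactly at 0 or
#' 1 are clipped to `[eps, 1 - eps]` so that the logit transform is finite.
#'
#' @param data A data frame with columns `y` and `s`.
#' @param eps Clipping bound applied to `s` before any logit transform.
#' @return A tibble with `y` as integer 0/1 and `s` as a double in (0, 1).
#' @examples
#' as_cohort(data.frame(y = c(1, 0, 1), s = c(0.8, 0.2, 0.6)))
#' @export
as_cohort <- function(data, eps = 1e-10) {
  if (!is.data.frame(data)) {
    stop("`data` must be a data frame with columns `y` and `s`.", call. = FALSE)
  }
  missing_cols <- setdiff(c("y", "s"), names(data))
  if (length(missing_cols) > 0) {
    stop("cohort is missing required column(s): ",
         paste0("`", missing_cols, "`", collapse = ", "), call. = FALSE)
  }
  y <- data$y
  s <- data$s
  if (is.logical(y)) y <- as.integer(y)
  if (!is.numeric(y) || !all(y %in% c(0L, 1L))) {
    stop("`y` must be binary 0/1 (1 = case, 0 = control).", call. = FALSE)
  }
  if (!is.numeric(s) || anyNA(s) || any(s < 0) || any(s > 1)) {
    stop("`s` must be numeric risks in [0, 1] with no missing values.",
         call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  out$y <- as.integer(y)
  out$s <- pmin(pmax(as.double(s), eps), 1 - eps)
  out
}

# class counts and prevalence; the common precondition for every estimator
cohort_stats <- function(data) {
  n <- nrow(data)
  n_case <- sum(data$y == 1L)
  list(n = n, n_case = n_case, n_control = n - n_case,
       prevalence = if (n > 0) n_case / n else NA_real_)
}

require_both_classes <- function(data, what = "this operation") {
  st <- cohort_stats(data)
  if (st$n_case == 0L) {
    stop("no cases (y = 1) in the cohort; ", what, " is undefined.",
         call. = FALSE)
  }
  if (st$n_control == 0L) {
    stop("no controls (y = 0) in the cohort; ", what, " is undefined.",
         call. = FALSE)
  }
  invisible(st)
}

#' Read a cohort from a delimited text file
#'
#' Reads a CSV or TSV file with a header containing at least the columns `y`
#' (0/1 outcome) and `s` (predicted risk). The delimiter is taken from the
#' file extension (`.tsv`/`.txt` are tab-delimited, everything else comma).
#'
#' @param path Path to the delimited file.
#' @inheritParams as_cohort
#' @return A validated cohort tibble (see [as_cohort()]).
#' @export
read_cohort <- function(path, eps = 1e-10) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  as_cohort(raw, eps = eps)
}

#' Write a cohort to a CSV file
#'
#' @param data A cohort data frame (columns `y`, `s`, optionally `p_true`).
#' @param path Output path; written as comma-separated text with a header.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path, progress = FALSE)
  invisible(path)
}
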