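#' @importFrom rlang .data
NULL

# local-linear fit of y on s, evaluated at `at`; returns values clipped to [0,1]
loess_event_rate <- function(data, at, span = 0.75) {
  if (length(unique(data$s)) < 20) {
    stop("need at least 20 distinct risk scores to smooth event rates.",
         call. = FALSE)
  }
  fit <- stats::loess(y ~ s, data = data, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  unname(pmin(pmax(stats::predict(fit, newdata = data.frame(s = at)), 0), 1))
}

#' Smoothed observed event rate per subject
#'
#' Fits a LOESS (local linear, span `span`) regression of the outcome on the
#' risk score and evaluates it at each subject's score, giving the smoothed
#' observed event rate o(S_i) used on the vertical axis of calibration plots
#' and inside the recalibration weight function. Fitted values are clipped to
#' \[0, 1\].
#'
#' @inheritParams snb_at_cutpoint
#' @param span LOESS span (fraction of neighbours used in each local fit).
#' @return Numeric vector of event rates, aligned with the rows of `data`.
#' @export
smoothed_event_rate <- function(data, span = 0.75) {
  data <- as_cohort(data)
  loess_event_rate(data, at = data$s, span = span)
}

#' Calibration curve of a risk score
#'
#' Smoothed observed event rate evaluated on an even grid spanning the
#' observed score range. A calibrated model has a curve on the identity line;
#' a curve below the identity means risks are overestimated.
#'
#' @inheritParams smoothed_event_rate
#' @param n_grid Number of grid points (at least 2).
#' @return A `cal_curve` object: tibble with columns `grid` and `observed`,
#'   carrying the scores as an attribute for the histogram panel of
#'   [autoplot.cal_curve()].
#' @export
calibration_curve <- function(data, n_grid = 100, span = 0.75) {
  data <- as_cohort(data)
  if (!is.numeric(n_grid) || length(n_grid) != 1 || n_grid < 2) {
    stop("`n_grid` must be a single integer >= 2.", call. = FALSE)
  }
  grid <- seq(min(data$s), max(data$s), length.out = as.integer(n_grid))
  out <- tibble::tibble(grid = grid,
                        observed = loess_event_rate(data, at = grid,
                                                    span = span))
  attr(out, "scores") <- data$s
  class(out) <- c("cal_curve", class(out))
  out
}

#' Plot a calibration curve with the identity reference
#'
#' @param object A `cal_curve`.
#' @param ... Unused.
#' @return A ggplot object: calibration curve, dashed identity line and a
#'   rug of the observed risk scores.
#' @export
autoplot.cal_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  scores <- attr(object, "scores")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$grid, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.5) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "predicted risk", y = "observed event rate") +
    ggplot2::theme_minimal()
  if (!is.null(scores)) {
    p <- p + ggplot2::geom_rug(data = tibble::tibble(grid = scores),
                               ggplot2::aes(x = .data$grid), inherit.aes = FALSE,
                               sides = "b", alpha = 0.2, length = ggplot2::unit(0.02, "npc"))
  }
  p
}

#' Specify a recalibration weight function
#'
#' The weight given to subject i is
#' \deqn{w_i = \exp\{-(o(S_i) - R)^2/\lambda\}}
#' when the smoothed event rate o(S_i) falls inside the critical risk
#' interval \[lower, upper\], and `delta` otherwise. Two practical forms:
#' `"exponential"` (interval defaults to \[0, 1\], so only `lambda` matters;
#' weight decays smoothly away from the threshold) and `"step"` (`lambda`
#' fixed large, default 10, so in-interval weights are near 1 and only
#' `delta` matters). As `lambda` grows all weights tend to 1 and weighted
#' recalibration approaches standard logistic recalibration.
#'
#' @param form `"exponential"` or `"step"`.
#' @param lambda Positive decay parameter.
#' @param delta Weight assigned outside the interval, in
#'   \[0, min in-interval weight\]. Required for the step form.
#' @param interval Critical risk interval `c(lower, upper)` on the event-rate
#'   axis; defaults to `c(0, 1)` for the exponential form.
#' @return A `weight_spec` object.
#' @examples
#' weight_spec("exponential", lambda = 0.01)
#' weight_spec("step", delta = 0.5, interval = c(0.1, 0.3))
#' @export
weight_spec <- function(form = c("exponential", "step"), lambda = NULL,
                        delta = NULL, interval = NULL) {
  form <- match.arg(form)
  if (form == "exponential") {
    if (is.null(lambda)) stop("exponential weights need `lambda`.", call. = FALSE)
    if (is.null(interval)) interval <- c(0, 1)
    if (is.null(delta)) delta <- 0
  } else {
    if (is.null(lambda)) lambda <- 10
    if (lambda < 10) stop("step-form weights require lambda >= 10.", call. = FALSE)
    if (is.null(delta)) stop("step weights need `delta`.", call. = FALSE)
    if (is.null(interval)) stop("step weights need a critical risk `interval`.",
                                call. = FALSE)
  }
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0) {
    stop("`lambda` must be a single positive number.", call. = FALSE)
  }
  if (!is.numeric(delta) || length(delta) != 1 || delta < 0) {
    stop("`delta` must be a single number >= 0.", call. = FALSE)
  }
  if (!is.numeric(interval) || length(interval) != 2 ||
      interval[1] > interval[2] || interval[1] < 0 || interval[2] > 1) {
    stop("`interval` must be c(lower, upper) with 0 <= lower <= upper <= 1.",
         call. = FALSE)
  }
  structure(list(form = form, lambda = lambda, delta = delta,
                 interval = interval),
            class = "weight_spec")
}

#' @export
print.weight_spec <- function(x, ...) {
  cat(sprintf("recalibration weights: %s form, lambda = %g, delta = %g, interval = [%g, %g]\n",
              x$form, x$lambda, x$delta, x$interval[1], x$interval[2]))
  invisible(x)
}

#' Evaluate recalibration weights
#'
#' @param event_rate Numeric vector of smoothed observed event rates o(S_i)
#'   (see [smoothed_event_rate()]). Non-finite entries (smoothing edge
#'   failures) receive weight `delta`.
#' @param spec A [weight_spec()].
#' @param threshold The clinical risk threshold R.
#' @return Numeric vector of weights in \[0, 1\].
#' @export
compute_weights <- function(event_rate, spec, threshold) {
  stopifnot(inherits(spec, "weight_spec"))
  check_threshold(threshold)
  # delta may not exceed the infimum of the in-interval weights
  lo <- exp(-max((spec$interval - threshold)^2) / spec$lambda)
  if (spec$delta > lo + 1e-12) {
    stop(sprintf(
      "`delta` = %g exceeds the minimum in-interval weight %g; shrink delta or widen lambda.",
      spec$delta, lo), call. = FALSE)
  }
  o <- as.double(event_rate)
  inside <- is.finite(o) & o >= spec$interval[1] & o <= spec$interval[2]
  w <- rep(spec$delta, length(o))
  w[inside] <- exp(-(o[inside] - threshold)^2 / spec$lambda)
  w
}

#' Attach smoothed event rates and weights to a cohort
#'
#' Convenience wrapper for pipelines: computes [smoothed_event_rate()] and
#' [compute_weights()] and appends them as columns `event_rate` and `weight`.
#'
#' @inheritParams smoothed_event_rate
#' @inheritParams compute_weights
#' @return The cohort tibble with two extra columns.
#' @export
add_weights <- function(data, spec, threshold, span = 0.75) {
  data <- as_cohort(data)
  data$event_rate <- smoothed_event_rate(data, span = span)
  data$weight <- compute_weights(data$event_rate, spec, threshold)
  data
}

#' Effective sample proportion of a weight vector
#'
#' The mean weight: the fraction of the sample's information retained after
#' down-weighting. Equals 1 under standard (unweighted) recalibration.
#'
#' @param w Numeric weights in \[0, 1\].
#' @return Scalar in \[0, 1\].
#' @export
effective_sample_proportion <- function(w) {
  if (length(w) == 0) stop("empty weight vector.", call. = FALSE)
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1)) {
    stop("weights must be finite and in [0, 1].", call. = FALSE)
  }
  mean(w)
}
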