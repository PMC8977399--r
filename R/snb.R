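#' @importFrom stats plogis qlogis
NULL

check_threshold <- function(threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1) {
    stop("`threshold` must be a single risk threshold strictly inside (0, 1).",
         call. = FALSE)
  }
  invisible(threshold)
}

check_interval <- function(interval, threshold) {
  if (is.null(interval)) return(invisible(NULL))
  if (!is.numeric(interval) || length(interval) != 2 ||
      interval[1] > interval[2] ||
      interval[1] < 0 || interval[2] > 1) {
    stop("`interval` must be c(lower, upper) with 0 <= lower <= upper <= 1.",
         call. = FALSE)
  }
  if (threshold < interval[1] || threshold > interval[2]) {
    stop("`threshold` must lie inside the critical risk interval.",
         call. = FALSE)
  }
  invisible(interval)
}

# discount factor multiplying FPR in sNB: ((1 - pi) / pi) * (R / (1 - R))
snb_discount <- function(prevalence, threshold) {
  ((1 - prevalence) / prevalence) * (threshold / (1 - threshold))
}

#' True- and false-positive rates of a risk score at one or more cutpoints
#'
#' A subject is assigned the intervention when their risk score strictly
#' exceeds the cutpoint; ties at the cutpoint are untreated.
#'
#' @param data A cohort data frame (see [as_cohort()]).
#' @param cutpoint Numeric vector of cutpoints in \[0, 1\].
#' @return A tibble with columns `cutpoint`, `tpr`, `fpr`, one row per
#'   cutpoint. Both rates are non-increasing in the cutpoint.
#' @examples
#' toy <- data.frame(y = rep(1:0, each = 4),
#'                   s = c(0.9, 0.6, 0.35, 0.2, 0.8, 0.3, 0.25, 0.1))
#' classification_rates(toy, 0.3)
#' @export
classification_rates <- function(data, cutpoint) {
  data <- as_cohort(data)
  st <- require_both_classes(data, "a classification rate")
  stopifnot(is.numeric(cutpoint), all(cutpoint >= 0), all(cutpoint <= 1))
  s_case <- sort(data$s[data$y == 1L])
  s_ctrl <- sort(data$s[data$y == 0L])
  # findInterval counts scores <= cutpoint, so n - count is the strict-">" tally
  tpr <- (st$n_case - findInterval(cutpoint, s_case)) / st$n_case
  fpr <- (st$n_control - findInterval(cutpoint, s_ctrl)) / st$n_control
  tibble::tibble(cutpoint = as.double(cutpoint), tpr = tpr, fpr = fpr)
}

#' Standardized net benefit of a thresholded risk score
#'
#' Computes sNB_r = TPR_r - (R/(1-R)) * ((1-pi)/pi) * FPR_r, where the
#' treatment rule is `s > r` and the harm-benefit weighting is fixed by the
#' clinical risk threshold `R`. At `cutpoint = threshold` this is the sNB of
#' the risk model itself; varying the cutpoint with `threshold` fixed traces
#' all sNB values attainable by (monotone) recalibration.
#'
#' @inheritParams classification_rates
#' @param threshold The clinically mandated risk threshold R in (0, 1).
#' @param cutpoint Cutpoint(s) r at which the treatment rule is applied;
#'   defaults to `threshold`.
#' @return A numeric vector of sNB values, one per cutpoint (maximum 1).
#' @examples
#' toy <- data.frame(y = rep(1:0, each = 4),
#'                   s = c(0.9, 0.6, 0.35, 0.2, 0.8, 0.3, 0.25, 0.1))
#' snb_at_cutpoint(toy, threshold = 0.3)  # sNB of the model at R = 0.3
#' @export
snb_at_cutpoint <- function(data, threshold, cutpoint = threshold) {
  check_threshold(threshold)
  rates <- classification_rates(data, cutpoint)
  st <- cohort_stats(as_cohort(data))
  unname(rates$tpr - snb_discount(st$prevalence, threshold) * rates$fpr)
}

#' Benefit-to-harm ratio implied by a risk threshold
#'
#' Under the decision-theoretic reading of a risk threshold R, treating at
#' risk above R encodes C/B = R/(1-R), so the benefit of intervening on a
#' case is (1-R)/R times the harm of intervening on a control.
#'
#' @inheritParams snb_at_cutpoint
#' @return The scalar benefit-to-harm ratio B/C = (1-R)/R.
#' @examples
#' harm_benefit_ratio(0.075)  # statin threshold: benefit ~ 12x harm
#' @export
harm_benefit_ratio <- function(threshold) {
  check_threshold(threshold)
  (1 - threshold) / threshold
}

#' Lower bound of the near-maximal sNB region (1-SE rule)
#'
#' @param snb_max Estimated maximum achievable sNB.
#' @param se_max Estimated standard error of `snb_max`.
#' @return `snb_max - se_max`, the bound below which a model is considered
#'   distinguishably worse than the best achievable recalibration.
#' @export
snb_constraint_bound <- function(snb_max, se_max) {
  stopifnot(is.numeric(snb_max), is.numeric(se_max), se_max >= 0)
  snb_max - se_max
}

#' Delta-method standard error of the maximum achievable sNB
#'
#' Evaluates, at the maximizing cutpoint of `curve`, the binomial-sampling
#' variance of the plug-in sNB with the prevalence held fixed:
#' \deqn{\hat\sigma^2 = TPR(1-TPR)/n_{case} + k^2\, FPR(1-FPR)/n_{control}}
#' with \eqn{k = ((1-\hat\pi)/\hat\pi)\,(R/(1-R))}.
#'
#' @inheritParams snb_at_cutpoint
#' @param curve An [snb_curve()] computed on `data` (used for its maximizing
#'   cutpoint).
#' @return The scalar standard error.
#' @export
max_snb_se <- function(data, curve, threshold) {
  check_threshold(threshold)
  data <- as_cohort(data)
  st <- require_both_classes(data, "the sNB standard error")
  r_star <- if (inherits(curve, "snb_curve")) curve$r_star else as.double(curve)
  rates <- classification_rates(data, r_star)
  k <- snb_discount(st$prevalence, threshold)
  sqrt(rates$tpr * (1 - rates$tpr) / st$n_case +
         k^2 * rates$fpr * (1 - rates$fpr) / st$n_control)
}

#' sNB-versus-cutpoint curve and the maximum achievable sNB
#'
#' Evaluates the sNB of the treatment rule `s > r` over all cutpoints r while
#' the harm-benefit ratio stays fixed at the clinical threshold R. Because
#' the rule only changes when r crosses an observed score, sNB_r is a step
#' function; the curve is evaluated at the exact knot grid (midpoints between
#' consecutive distinct scores, plus 0 and 1), which attains the exact
#' maximum. The maximum of the curve estimates the sNB the risk model would
#' have if it were calibrated at R, i.e. the best sNB achievable by any
#' monotone recalibration.
#'
#' @inheritParams snb_at_cutpoint
#' @return An object of class `snb_curve`: a list with `curve` (tibble of
#'   `cutpoint`, `snb`), `r_star` (maximizing cutpoint; ties broken toward
#'   R), `snb_max`, `se_max`, `snb_at_R`, `threshold`, and the class counts.
#' @examples
#' set.seed(1)
#' p <- rbeta(500, 2, 5)
#' dat <- data.frame(y = rbinom(500, 1, p), s = p)
#' sc <- snb_curve(dat, threshold = 0.3)
#' sc$snb_max - sc$snb_at_R  # potential gain from recalibration
#' @export
snb_curve <- function(data, threshold) {
  check_threshold(threshold)
  data <- as_cohort(data)
  st <- require_both_classes(data, "the sNB curve")
  s_sorted <- sort(unique(data$s))
  if (length(s_sorted) < 2) {
    stop("need at least 2 distinct risk scores to trace the sNB curve.",
         call. = FALSE)
  }
  mids <- (s_sorted[-1] + s_sorted[-length(s_sorted)]) / 2
  grid <- sort(unique(c(0, mids, 1)))
  snb <- snb_at_cutpoint(data, threshold, cutpoint = grid)
  snb_max <- max(snb)
  # ties at the max resolved toward the cutpoint closest to R (smallest shift)
  at_max <- which(snb >= snb_max - 1e-12)
  r_star <- grid[at_max[which.min(abs(grid[at_max] - threshold))]]
  out <- structure(
    list(curve = tibble::tibble(cutpoint = grid, snb = snb),
         r_star = r_star,
         snb_max = snb_max,
         snb_at_R = snb_at_cutpoint(data, threshold),
         threshold = threshold,
         n = st$n, n_case = st$n_case, n_control = st$n_control,
         prevalence = st$prevalence),
    class = "snb_curve")
  out$se_max <- max_snb_se(data, out, threshold)
  out
}

#' @export
print.snb_curve <- function(x, ...) {
  cat("sNB-vs-cutpoint curve (risk threshold R =", format(x$threshold), ")\n")
  cat(sprintf("  n = %d (%d cases / %d controls), grid of %d cutpoints\n",
              x$n, x$n_case, x$n_control, nrow(x$curve)))
  cat(sprintf("  sNB at R        : %.4f\n", x$snb_at_R))
  cat(sprintf("  max achievable  : %.4f at cutpoint %.4f (SE %.4f)\n",
              x$snb_max, x$r_star, x$se_max))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.snb_curve <- function(x, ...) x$curve

#' @export
glance.snb_curve <- function(x, ...) {
  tibble::tibble(snb_at_R = x$snb_at_R, snb_max = x$snb_max,
                 r_star = x$r_star, se_max = x$se_max,
                 threshold = x$threshold, n = x$n,
                 prevalence = x$prevalence)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an sNB-vs-cutpoint curve
#'
#' Draws the step curve of achievable sNB against the cutpoint, the clinical
#' threshold R (vertical line), and a dotted horizontal line one standard
#' error below the maximum (the 1-SE reference used to judge whether a model
#' is near-optimal).
#'
#' @param object An `snb_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.snb_curve <- function(object, ...) {
  df <- object$curve
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cutpoint, y = .data$snb)) +
    ggplot2::geom_step(linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = object$snb_max - object$se_max,
                        linetype = "dotted") +
    ggplot2::geom_vline(xintercept = object$threshold,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::annotate("point", x = object$threshold, y = object$snb_at_R,
                      shape = 19) +
    ggplot2::labs(x = "cutpoint r", y = "standardized net benefit",
                  title = "Potential sNB under recalibration",
                  subtitle = sprintf(
                    "sNB at R = %.3f; max achievable = %.3f (SE %.3f)",
                    object$snb_at_R, object$snb_max, object$se_max)) +
    ggplot2::theme_minimal()
}
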