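#' Monotone piecewise-polynomial map on \[0, 1\]
#'
#' A map is stored as breakpoints `breaks` and one polynomial per segment,
#' coefficients in ascending powers of `(x - breaks[j])`. The constructor
#' validates that the map is non-decreasing with range inside \[0, 1\] on a
#' 10^4-point grid; non-monotone maps are rejected because they would change
#' the ranking of risks, not merely miscalibrate them.
#'
#' @param breaks Increasing breakpoints spanning \[0, 1\]
#'   (`breaks[1] = 0`, `breaks[length(breaks)] = 1`).
#' @param coefs A list with one numeric coefficient vector per segment
#'   (length `length(breaks) - 1`), ascending powers.
#' @return A `piecewise_poly` object, callable through [map_eval()].
#' @examples
#' # single quartic segment: identity plus a monotone bump
#' piecewise_poly(c(0, 1), list(c(0, 1)))  # the identity map
#' @export
piecewise_poly <- function(breaks, coefs) {
  stopifnot(is.numeric(breaks), length(breaks) >= 2, !is.unsorted(breaks),
            is.list(coefs), length(coefs) == length(breaks) - 1)
  obj <- structure(list(breaks = as.double(breaks), coefs = coefs),
                   class = "piecewise_poly")
  grid <- seq(breaks[1], breaks[length(breaks)], length.out = 1e4)
  v <- map_eval_raw(obj, grid)
  if (any(diff(v) < -1e-9)) {
    stop("piecewise polynomial map is not monotone non-decreasing.",
         call. = FALSE)
  }
  if (min(v) < -1e-9 || max(v) > 1 + 1e-9) {
    stop("piecewise polynomial map must take values in [0, 1].", call. = FALSE)
  }
  obj
}

#' Evaluate a piecewise-polynomial map
#'
#' @param map A `piecewise_poly`.
#' @param x Numeric vector in \[0, 1\].
#' @return `map(x)`, clipped to \[0, 1\].
#' @export
map_eval <- function(map, x) {
  pmin(pmax(map_eval_raw(map, x), 0), 1)
}

# unclipped evaluation; the constructor validates on this so that clipping
# cannot mask a non-monotone or out-of-range polynomial
map_eval_raw <- function(map, x) {
  stopifnot(inherits(map, "piecewise_poly"))
  b <- map$breaks
  seg <- pmin(pmax(findInterval(x, b), 1L), length(b) - 1L)
  out <- numeric(length(x))
  for (j in unique(seg)) {
    idx <- seg == j
    t <- x[idx] - b[j]
    cf <- map$coefs[[j]]
    acc <- 0
    for (k in rev(seq_along(cf))) acc <- acc * t + cf[k]
    out[idx] <- acc
  }
  out
}

# Fritsch-Carlson monotone cubic Hermite interpolation through (x, y),
# returned with explicit per-segment coefficients
monotone_cubic_map <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2, !is.unsorted(x),
            !is.unsorted(y))
  n <- length(x)
  h <- diff(x); d <- diff(y) / h
  m <- numeric(n)
  m[1] <- d[1]; m[n] <- d[n - 1]
  if (n > 2) {
    for (k in 2:(n - 1)) {
      m[k] <- if (d[k - 1] * d[k] <= 0) 0 else (d[k - 1] + d[k]) / 2
    }
  }
  for (k in seq_len(n - 1)) {
    if (d[k] == 0) {
      m[k] <- 0; m[k + 1] <- 0
    } else {
      a <- m[k] / d[k]; bb <- m[k + 1] / d[k]
      r <- a^2 + bb^2
      if (r > 9) {
        t <- 3 / sqrt(r)
        m[k] <- t * a * d[k]
        m[k + 1] <- t * bb * d[k]
      }
    }
  }
  coefs <- vector("list", n - 1)
  for (k in seq_len(n - 1)) {
    c2 <- (3 * d[k] - 2 * m[k] - m[k + 1]) / h[k]
    c3 <- (m[k] + m[k + 1] - 2 * d[k]) / h[k]^2
    coefs[[k]] <- c(y[k], m[k], c2, c3)
  }
  piecewise_poly(x, coefs)
}

#' Specify a simulation scenario for miscalibrated risk scores
#'
#' The generative model: a subject's true risk p is drawn from a mixture of
#' Beta distributions (components representing low-, medium- and high-risk
#' subpopulations), the outcome is Bernoulli(p), and the observed risk score
#' is a monotone piecewise-polynomial distortion of p. The mixture mean
#' `sum(mixing * alpha/(alpha + beta))` is the event rate of the population.
#'
#' @param shapes A list of `c(alpha, beta)` Beta shape pairs, one per
#'   component.
#' @param mixing Mixing proportions, same length as `shapes`, summing to 1.
#' @param miscal A `piecewise_poly` miscalibration map, a 2-column matrix of
#'   control points (interpolated by a monotone cubic), or `NULL` for the
#'   identity (a calibrated score).
#' @param name Label for the scenario.
#' @param threshold Risk threshold the scenario is designed around.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(shapes, mixing, miscal = NULL, name = "custom",
                          threshold = 0.3) {
  stopifnot(is.list(shapes), length(shapes) >= 1)
  ok_shape <- vapply(shapes, function(sh) {
    is.numeric(sh) && length(sh) == 2 && all(sh > 0)
  }, logical(1))
  if (!all(ok_shape)) {
    stop("each Beta component needs two positive shape parameters.",
         call. = FALSE)
  }
  mixing <- as.double(mixing)
  if (length(mixing) != length(shapes) || any(mixing < 0) ||
      abs(sum(mixing) - 1) > 1e-8) {
    stop("`mixing` must be non-negative proportions summing to 1, one per component.",
         call. = FALSE)
  }
  if (is.matrix(miscal) || is.data.frame(miscal)) {
    miscal <- monotone_cubic_map(miscal[, 1], miscal[, 2])
  }
  if (!is.null(miscal) && !inherits(miscal, "piecewise_poly")) {
    stop("`miscal` must be a piecewise_poly, a matrix of control points, or NULL.",
         call. = FALSE)
  }
  check_threshold(threshold)
  structure(list(shapes = shapes, mixing = mixing, miscal = miscal,
                 name = name, threshold = threshold),
            class = "scenario_spec")
}

#' Population mean true risk of a scenario
#'
#' @param spec A [scenario_spec()].
#' @return `sum_m b_m * alpha_m / (alpha_m + beta_m)`, the expected event
#'   rate of the simulated population.
#' @export
scenario_mean_risk <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  means <- vapply(spec$shapes, function(sh) sh[1] / (sh[1] + sh[2]), numeric(1))
  sum(spec$mixing * means)
}

# shared default mixture: low / medium / high risk subpopulations
default_mixture <- function() {
  list(shapes = list(c(2, 10), c(6, 9), c(9, 4)),
       mixing = c(0.45, 0.35, 0.20))
}

# Control points of the four archetype miscalibration maps (around R = 0.3).
# Miscalibration near the threshold is deliberately strong enough to shift
# who crosses it (the implied treatment rule s > 0.3 corresponds to a true
# cutoff well away from 0.3), since sNB is only second-order sensitive to
# small cutoff shifts and a consequential scenario needs a visible sNB loss.
archetype_knots <- list(
  # scores underestimate risk near R, overestimate far from it
  example1 = cbind(c(0, 0.08, 0.50, 0.75, 1),
                   c(0, 0.13, 0.30, 0.82, 1)),
  # scores underestimate risk everywhere
  example2 = cbind(c(0, 0.30, 0.60, 1),
                   c(0, 0.15, 0.40, 1)),
  # scores overestimate risk near R, underestimate far from it
  example3 = cbind(c(0, 0.10, 0.20, 0.45, 0.80, 1),
                   c(0, 0.04, 0.30, 0.50, 0.72, 1)),
  # scores overestimate risk everywhere
  example4 = cbind(c(0, 0.15, 0.50, 1),
                   c(0, 0.30, 0.68, 1))
)

#' Built-in miscalibration scenarios
#'
#' Four archetypes of miscalibration around a threshold of R = 0.3:
#' `example1` underestimates risk near the threshold and overestimates
#' elsewhere; `example2` underestimates everywhere; `example3` overestimates
#' near the threshold and underestimates far from it; `example4`
#' overestimates everywhere. All four share a three-component Beta mixture
#' of true risks (low/medium/high-risk subpopulations). Any field may be
#' overridden, so externally supplied mixture or map parameters can replace
#' the presets.
#'
#' @param name One of `"example1"`..`"example4"`, or `"calibrated"` (identity
#'   map).
#' @param shapes,mixing,miscal,threshold Optional overrides passed to
#'   [scenario_spec()].
#' @return A `scenario_spec`.
#' @examples
#' spec <- make_scenario("example1")
#' scenario_mean_risk(spec)
#' @export
make_scenario <- function(name, shapes = NULL, mixing = NULL, miscal = NULL,
                          threshold = 0.3) {
  valid <- c(names(archetype_knots), "calibrated")
  if (!is.character(name) || length(name) != 1 || !name %in% valid) {
    stop("unknown scenario; valid names: ", paste(valid, collapse = ", "),
         call. = FALSE)
  }
  mix <- default_mixture()
  if (is.null(shapes)) shapes <- mix$shapes
  if (is.null(mixing)) mixing <- mix$mixing
  if (is.null(miscal) && name != "calibrated") {
    miscal <- monotone_cubic_map(archetype_knots[[name]][, 1],
                                 archetype_knots[[name]][, 2])
  }
  scenario_spec(shapes, mixing, miscal, name = name, threshold = threshold)
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("simulation scenario '%s' (R = %g)\n", x$name, x$threshold))
  for (m in seq_along(x$shapes)) {
    cat(sprintf("  component %d: Beta(%g, %g), mixing %.2f\n", m,
                x$shapes[[m]][1], x$shapes[[m]][2], x$mixing[m]))
  }
  cat(sprintf("  mean true risk %.3f; miscalibration: %s\n",
              scenario_mean_risk(x),
              if (is.null(x$miscal)) "none (calibrated)" else
                sprintf("piecewise polynomial, %d segment(s)",
                        length(x$miscal$coefs))))
  invisible(x)
}

#' Draw true risks from a scenario's Beta mixture
#'
#' @param spec A [scenario_spec()].
#' @param n Number of subjects.
#' @param seed Optional integer seed.
#' @return Numeric vector of true risks in (0, 1).
#' @export
sample_true_risks <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"), n >= 0)
  run <- function() {
    if (n == 0) return(numeric(0))
    comp <- sample.int(length(spec$mixing), n, replace = TRUE,
                       prob = spec$mixing)
    a <- vapply(spec$shapes, `[[`, numeric(1), 1)[comp]
    b <- vapply(spec$shapes, `[[`, numeric(1), 2)[comp]
    stats::rbeta(n, a, b)
  }
  if (!is.null(seed)) withr::with_seed(as.integer(seed), run()) else run()
}

#' Draw Bernoulli outcomes from true risks
#'
#' @param p True risks in \[0, 1\].
#' @param seed Optional integer seed.
#' @return Integer vector of 0/1 outcomes.
#' @export
sample_outcomes <- function(p, seed = NULL) {
  stopifnot(is.numeric(p), all(p >= 0), all(p <= 1))
  run <- function() stats::rbinom(length(p), 1L, p)
  if (!is.null(seed)) withr::with_seed(as.integer(seed), run()) else run()
}

#' Distort true risks into miscalibrated risk scores
#'
#' @param p True risks.
#' @param spec A [scenario_spec()]; the identity is used when the scenario
#'   carries no miscalibration map.
#' @return Risk scores `map(p)`, preserving the rank order of `p`.
#' @export
apply_miscalibration <- function(p, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(spec$miscal)) return(as.double(p))
  map_eval(spec$miscal, p)
}

#' Simulate a cohort under a miscalibration scenario
#'
#' Draws true risks from the Beta mixture, outcomes from Bernoulli(p), and
#' observed risk scores by passing the true risks through the scenario's
#' miscalibration map.
#'
#' @inheritParams sample_true_risks
#' @return A cohort tibble with columns `y`, `s` and `p_true`.
#' @examples
#' dat <- simulate_cohort(make_scenario("example1"), n = 1000, seed = 7)
#' snb_at_cutpoint(dat, threshold = 0.3)
#' @export
simulate_cohort <- function(spec, n, seed = NULL) {
  run <- function() {
    p <- sample_true_risks(spec, n)
    y <- sample_outcomes(p)
    tibble::tibble(y = y, s = pmin(pmax(apply_miscalibration(p, spec), 1e-10),
                                   1 - 1e-10),
                   p_true = p)
  }
  if (!is.null(seed)) withr::with_seed(as.integer(seed), run()) else run()
}
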