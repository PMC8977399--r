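# shared fixtures and independent oracles

# 4 cases / 4 controls with hand-countable threshold exceedances
toy_cohort <- function() {
  data.frame(y = rep(1:0, each = 4),
             s = c(0.9, 0.6, 0.35, 0.2, 0.8, 0.3, 0.25, 0.1))
}

# calibrated cohort: y ~ Bernoulli(s) with s from a Beta distribution
calibrated_cohort <- function(n, shape1 = 2, shape2 = 5, seed = 1) {
  withr::with_seed(seed, {
    s <- stats::rbeta(n, shape1, shape2)
    data.frame(y = stats::rbinom(n, 1, s), s = s)
  })
}

# brute-force sNB maximum: evaluate the treatment rule s > r at every
# observed score and at 0 and 1 (the step function changes only at scores)
brute_force_snb_max <- function(data, threshold) {
  y <- data$y; s <- data$s
  prev <- mean(y)
  k <- ((1 - prev) / prev) * (threshold / (1 - threshold))
  cuts <- sort(unique(c(0, s, 1)))
  vals <- vapply(cuts, function(r) {
    mean(s[y == 1] > r) - k * mean(s[y == 0] > r)
  }, numeric(1))
  max(vals)
}

# plug-in sNB of a recalibration map, written directly from its defining
# indicator form (cases and controls averaged separately)
plugin_snb <- function(data, alpha0, alpha1, threshold) {
  z <- stats::qlogis(pmin(pmax(data$s, 1e-10), 1 - 1e-10))
  p <- stats::plogis(alpha0 + alpha1 * z)
  prev <- mean(data$y)
  k <- ((1 - prev) / prev) * (threshold / (1 - threshold))
  mean(p[data$y == 1] > threshold) - k * mean(p[data$y == 0] > threshold)
}

# weighted Bernoulli log-likelihood, written independently of the package
wloglik_oracle <- function(alpha0, alpha1, data, w) {
  z <- stats::qlogis(pmin(pmax(data$s, 1e-10), 1 - 1e-10))
  p <- stats::plogis(alpha0 + alpha1 * z)
  sum(w * (data$y * log(p) + (1 - data$y) * log(1 - p)))
}

# two-stage independent grid maximizer of the weighted log-likelihood
grid_max_wloglik <- function(data, w, a0_range = c(-4, 4),
                             a1_range = c(0.05, 4)) {
  stage <- function(a0s, a1s) {
    best <- c(NA, NA, -Inf)
    for (a0 in a0s) {
      ll <- vapply(a1s, function(a1) wloglik_oracle(a0, a1, data, w),
                   numeric(1))
      j <- which.max(ll)
      if (ll[j] > best[3]) best <- c(a0, a1s[j], ll[j])
    }
    best
  }
  coarse <- stage(seq(a0_range[1], a0_range[2], by = 0.1),
                  seq(a1_range[1], a1_range[2], by = 0.05))
  fine <- stage(seq(coarse[1] - 0.15, coarse[1] + 0.15, by = 0.002),
                seq(max(1e-4, coarse[2] - 0.1), coarse[2] + 0.1, by = 0.002))
  list(alpha0 = fine[1], alpha1 = fine[2], loglik = fine[3])
}
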