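test_that("the recalibration map is the two-parameter logistic family", {
  s <- c(0.05, 0.2, 0.5, 0.8, 0.99)
  expect_equal(apply_recal(c(0, 1), s), s, tolerance = 1e-9)

  # published standard-recalibration intercept applied at s = 0.5
  expect_equal(apply_recal(c(-0.911, 0.856), 0.5), plogis(-0.911),
               tolerance = 1e-12)

  # composing two maps composes affinely on the logit scale
  b <- c(0.4, 1.3); a <- c(-0.7, 0.8)
  expect_equal(apply_recal(a, apply_recal(b, s)),
               apply_recal(c(a[1] + a[2] * b[1], a[2] * b[2]), s),
               tolerance = 1e-9)

  # monotone, in (0,1), rank preserving
  out <- apply_recal(c(1.2, 0.4), sort(s))
  expect_true(all(diff(out) > 0))
  expect_true(all(out > 0 & out < 1))

  expect_error(apply_recal(c(0, -1), s), "positive")
  expect_error(apply_recal(c(0, 0), s), "positive")
})

test_that("standard recalibration recovers generating parameters", {
  # calibrated scores: (alpha0, alpha1) = (0, 1)
  dat <- calibrated_cohort(50000, seed = 31)
  fit <- fit_standard(dat)
  ref <- stats::glm(y ~ qlogis(s), family = binomial, data = dat)
  se <- sqrt(diag(stats::vcov(ref)))
  expect_true(fit$converged)
  expect_lt(abs(fit$alpha0 - 0), 3 * se[1])
  expect_lt(abs(fit$alpha1 - 1), 3 * se[2])
  # and matches the glm solution (independent fitting route)
  expect_equal(unname(c(fit$alpha0, fit$alpha1)), unname(coef(ref)),
               tolerance = 1e-5)

  # systematic logit-shift overestimation inverts to alpha0 = -1
  dat2 <- withr::with_seed(32, {
    p <- stats::rbeta(50000, 2, 5)
    data.frame(y = stats::rbinom(50000, 1, p), s = plogis(qlogis(p) + 1))
  })
  fit2 <- fit_standard(dat2)
  ref2 <- stats::glm(y ~ qlogis(s), family = binomial, data = dat2)
  se2 <- sqrt(diag(stats::vcov(ref2)))
  expect_lt(abs(fit2$alpha0 + 1), 3 * se2[1])
  expect_lt(abs(fit2$alpha1 - 1), 3 * se2[2])
})

test_that("degenerate cohorts are rejected and separation is flagged", {
  expect_error(fit_standard(data.frame(y = rep(1L, 30),
                                       s = runif(30, 0.2, 0.8))), "controls")
  sep <- data.frame(y = rep(1:0, each = 20),
                    s = c(runif(20, 0.6, 0.9), runif(20, 0.1, 0.4)))
  fit <- fit_standard(sep)
  expect_false(fit$converged)
})

test_that("weighted recalibration with unit weights equals the standard fit", {
  dat <- calibrated_cohort(2000, seed = 33)
  std <- fit_standard(dat)
  wt <- fit_weighted(dat, rep(1, nrow(dat)))
  expect_equal(wt$alpha0, std$alpha0, tolerance = 1e-6)
  expect_equal(wt$alpha1, std$alpha1, tolerance = 1e-6)
  expect_equal(wt$effective_sample_proportion, 1)
})

test_that("weighted recalibration matches an independent grid maximizer", {
  dat <- calibrated_cohort(40, seed = 34)
  w <- withr::with_seed(35, runif(40, 0.2, 1))
  fit <- fit_weighted(dat, w)
  oracle <- grid_max_wloglik(dat, w)
  expect_lt(abs(fit$alpha0 - oracle$alpha0), 1e-2)
  expect_lt(abs(fit$alpha1 - oracle$alpha1), 1e-2)
  expect_gte(fit$loglik, oracle$loglik - 1e-6)
  expect_equal(fit$effective_sample_proportion, mean(w))
})

test_that("zero-weight subjects cannot influence the weighted fit", {
  dat <- calibrated_cohort(300, seed = 36)
  w <- as.numeric(dat$s > 0.2 & dat$s < 0.6)
  fit <- fit_weighted(dat, w)
  flipped <- dat
  flipped$y[w == 0] <- 1L - flipped$y[w == 0]
  fit2 <- fit_weighted(flipped, w)
  expect_equal(fit$alpha0, fit2$alpha0, tolerance = 1e-8)
  expect_equal(fit$alpha1, fit2$alpha1, tolerance = 1e-8)
})

test_that("weighted fit refuses an effectively empty sample", {
  dat <- calibrated_cohort(200, seed = 37)
  expect_error(fit_weighted(dat, rep(0.01, 200)), "effective sample")
})

test_that("constrained recalibration returns the standard solution when feasible", {
  # near-calibrated data: the standard fit's induced cutpoint clears the bound
  dat <- calibrated_cohort(2000, seed = 38)
  std <- fit_standard(dat)
  con <- fit_constrained(dat, threshold = 0.3)
  expect_identical(con$method, "constrained")
  expect_identical(con$alpha0, std$alpha0)
  expect_identical(con$alpha1, std$alpha1)
})

test_that("constrained recalibration is feasible, concave-optimal and likelihood-ordered", {
  spec <- make_scenario("example1")
  dat <- simulate_cohort(spec, 1500, seed = 39)
  std <- fit_standard(dat)
  con <- fit_constrained(dat, threshold = 0.3)
  curve <- snb_curve(dat, threshold = 0.3)

  # feasibility postcondition: within 1 SE of the maximum achievable sNB
  expect_gte(snb_of_model(dat, con, 0.3),
             curve$snb_max - curve$se_max - 1e-9)
  expect_equal(con$constraint_bound, curve$snb_max - curve$se_max)

  # constrained likelihood can never exceed the unconstrained one
  expect_lte(con$loglik, std$loglik + 1e-8)

  # when the standard solution is infeasible the constrained one buys sNB
  if (snb_of_model(dat, std, 0.3) < con$constraint_bound) {
    expect_gt(snb_of_model(dat, con, 0.3), snb_of_model(dat, std, 0.3))
  }
})

test_that("constrained recalibration matches a feasibility-restricted grid search", {
  spec <- make_scenario("example3")
  for (seed in c(41, 42)) {
    dat <- simulate_cohort(spec, 60, seed = seed)
    con <- fit_constrained(dat, threshold = 0.3)
    bound <- con$constraint_bound
    # brute force over (alpha0, alpha1), keeping only feasible points
    a0s <- seq(-4, 4, by = 0.05); a1s <- seq(0.05, 4, by = 0.05)
    best <- -Inf
    for (a0 in a0s) {
      for (a1 in a1s) {
        if (plugin_snb(dat, a0, a1, 0.3) >= bound) {
          ll <- wloglik_oracle(a0, a1, dat, rep(1, nrow(dat)))
          if (ll > best) best <- ll
        }
      }
    }
    expect_gte(con$loglik, best - 1e-2)
    expect_gte(plugin_snb(dat, con$alpha0, con$alpha1, 0.3), bound - 1e-9)
  }
})

test_that("plug-in sNB of a fitted map equals sNB of the recalibrated scores at R", {
  spec <- make_scenario("example2")
  dat <- simulate_cohort(spec, 800, seed = 43)
  for (fit in list(fit_standard(dat), fit_constrained(dat, 0.3))) {
    expect_equal(snb_of_model(dat, fit, 0.3),
                 plugin_snb(dat, fit$alpha0, fit$alpha1, 0.3),
                 tolerance = 1e-12)
  }
})

test_that("every fitted model has a positive slope and preserves ranks", {
  spec <- make_scenario("example4")
  for (seed in 44:46) {
    dat <- simulate_cohort(spec, 600, seed = seed)
    fits <- list(fit_standard(dat),
                 fit_weighted(dat, compute_weights(
                   smoothed_event_rate(dat),
                   weight_spec("exponential", lambda = 0.05), 0.3)),
                 fit_constrained(dat, 0.3))
    for (fit in fits) {
      expect_gt(fit$alpha1, 0)
      rec <- apply_recal(fit, dat$s)
      expect_equal(order(rec), order(dat$s))
    }
  }
})

test_that("fit_recal dispatches and recalibrate appends scores", {
  dat <- calibrated_cohort(500, seed = 47)
  m <- fit_recal(dat, "standard")
  expect_identical(m$method, "standard")
  out <- recalibrate(dat, m)
  expect_true("s_recal" %in% names(out))
  expect_equal(out$s_recal, apply_recal(m, dat$s))
  td <- tidy(m)
  expect_equal(td$estimate, c(m$alpha0, m$alpha1))
  expect_identical(glance(m)$method, "standard")
  expect_error(fit_recal(dat, "weighted"), "spec")
})
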