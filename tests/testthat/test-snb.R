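test_that("classification rates match hand counts and use a strict rule", {
  toy <- toy_cohort()
  r <- classification_rates(toy, 0.3)
  expect_equal(r$tpr, 0.75)   # cases 0.9, 0.6, 0.35 exceed 0.3
  expect_equal(r$fpr, 0.25)   # only control 0.8 exceeds 0.3

  # ties at the cutpoint are untreated: control at exactly 0.3 not counted
  expect_equal(classification_rates(toy, 0.3 - 1e-9)$fpr, 0.5)

  # nothing exceeds a cutpoint of 1
  r1 <- classification_rates(toy, 1)
  expect_equal(c(r1$tpr, r1$fpr), c(0, 0))

  # perfectly separated data
  sep <- data.frame(y = rep(1:0, each = 3), s = c(0.8, 0.7, 0.6, 0.3, 0.2, 0.1))
  rs <- classification_rates(sep, 0.45)
  expect_equal(c(rs$tpr, rs$fpr), c(1, 0))

  expect_error(classification_rates(data.frame(y = c(1, 1), s = c(0.2, 0.4)),
                                    0.3), "controls")
  expect_error(classification_rates(data.frame(y = c(0, 0), s = c(0.2, 0.4)),
                                    0.3), "cases")
})

test_that("classification rates are componentwise non-increasing in the cutpoint", {
  dat <- calibrated_cohort(300, seed = 4)
  grid <- seq(0, 1, by = 0.01)
  r <- classification_rates(dat, grid)
  expect_true(all(diff(r$tpr) <= 1e-12))
  expect_true(all(diff(r$fpr) <= 1e-12))
})

test_that("sNB at a cutpoint follows its defining formula", {
  toy <- toy_cohort()
  # tpr - (R/(1-R)) * ((1-pi)/pi) * fpr with pi = 1/2
  expect_equal(snb_at_cutpoint(toy, threshold = 0.3),
               0.75 - (0.3 / 0.7) * 0.25, tolerance = 1e-12)
  expect_equal(snb_at_cutpoint(toy, threshold = 0.3, cutpoint = 1), 0)

  # a perfect model attains the theoretical maximum of 1 for any pi and R
  for (spec in list(c(5, 15, 0.2), c(30, 10, 0.6), c(3, 40, 0.075))) {
    dat <- data.frame(y = rep(1:0, c(spec[1], spec[2])),
                      s = rep(c(0.9, 0.05), c(spec[1], spec[2])))
    expect_equal(snb_at_cutpoint(dat, threshold = spec[3]), 1)
  }
})

test_that("benefit-to-harm ratio is (1-R)/R", {
  expect_equal(harm_benefit_ratio(0.075), (1 - 0.075) / 0.075)
  expect_equal(harm_benefit_ratio(0.5), 1)
  expect_equal(harm_benefit_ratio(0.3), 7 / 3)
  expect_error(harm_benefit_ratio(0), "threshold")
  expect_error(harm_benefit_ratio(1), "threshold")
})

test_that("the sNB curve attains the brute-force maximum over all cutpoints", {
  for (seed in 1:5) {
    dat <- calibrated_cohort(150, seed = seed)
    sc <- snb_curve(dat, threshold = 0.3)
    expect_equal(sc$snb_max, brute_force_snb_max(dat, 0.3), tolerance = 1e-12)
  }
  toy <- toy_cohort()
  sc <- snb_curve(toy, threshold = 0.3)
  expect_equal(sc$snb_max, brute_force_snb_max(toy, 0.3), tolerance = 1e-12)
  expect_gte(sc$snb_max, 0.643)
})

test_that("sNB curve invariants hold", {
  dat <- calibrated_cohort(400, seed = 7)
  sc <- snb_curve(dat, threshold = 0.25)
  expect_true(all(sc$curve$snb <= 1 + 1e-12))
  expect_gte(sc$snb_max, sc$snb_at_R)
  expect_gte(sc$snb_max, max(sc$curve$snb) - 1e-12)
  expect_equal(sc$curve$snb[sc$curve$cutpoint == 1], 0)

  # everyone below the threshold: nobody treated at R
  low <- data.frame(y = rep(1:0, each = 10),
                    s = runif(20, 0.01, 0.15))
  expect_equal(snb_at_cutpoint(low, threshold = 0.5), 0)

  # perfectly discriminating, calibrated-side case: max 1, cutpoint separates
  sep <- data.frame(y = rep(1:0, each = 10),
                    s = c(seq(0.6, 0.9, length.out = 10),
                          seq(0.05, 0.3, length.out = 10)))
  ssc <- snb_curve(sep, threshold = 0.4)
  expect_equal(ssc$snb_max, 1)
  expect_gt(ssc$r_star, 0.3)
  expect_lt(ssc$r_star, 0.6 + 1e-9)

  expect_error(snb_curve(data.frame(y = c(1, 0), s = c(0.4, 0.4)), 0.3),
               "distinct")
})

test_that("argmax ties break toward the cutpoint nearest the threshold", {
  # with pi = 1/2 and R = 0.5 the discount is 1, so "treat both cases plus
  # one control" (cutpoint 0.225) ties with "treat the top case only"
  # (cutpoint 0.75) at sNB = 0.5; 0.75 is nearer the threshold
  dat <- data.frame(y = c(1, 1, 0, 0), s = c(0.9, 0.35, 0.6, 0.1))
  sc <- snb_curve(dat, threshold = 0.5)
  tied <- sc$curve$cutpoint[abs(sc$curve$snb - sc$snb_max) < 1e-12]
  expect_gt(length(tied), 1)
  expect_equal(sc$r_star, 0.75)
})

test_that("the delta-method SE of the maximum matches hand arithmetic and zeroes out under separation", {
  toy <- toy_cohort()
  sc <- snb_curve(toy, threshold = 0.3)
  r <- classification_rates(toy, sc$r_star)
  k <- ((1 - 0.5) / 0.5) * (0.3 / 0.7)
  expect_equal(sc$se_max,
               sqrt(r$tpr * (1 - r$tpr) / 4 + k^2 * r$fpr * (1 - r$fpr) / 4),
               tolerance = 1e-12)

  sep <- data.frame(y = rep(1:0, each = 5),
                    s = c(seq(0.7, 0.9, length.out = 5),
                          seq(0.1, 0.3, length.out = 5)))
  expect_equal(snb_curve(sep, threshold = 0.4)$se_max, 0)
})

test_that("the delta-method SE agrees with a bootstrap SE of the curve maximum", {
  dat <- calibrated_cohort(2000, shape1 = 2, shape2 = 5, seed = 10)
  sc <- snb_curve(dat, threshold = 0.3)
  boot_max <- withr::with_seed(99, {
    vapply(seq_len(600), function(b) {
      idx <- sample.int(nrow(dat), replace = TRUE)
      if (length(unique(dat$y[idx])) < 2) return(NA_real_)
      brute_force_snb_max(dat[idx, ], 0.3)
    }, numeric(1))
  })
  se_boot <- stats::sd(boot_max, na.rm = TRUE)
  expect_lt(abs(sc$se_max - se_boot) / se_boot, 0.25)
})

test_that("tidy, glance and autoplot expose curve results", {
  sc <- snb_curve(toy_cohort(), threshold = 0.3)
  expect_named(tidy(sc), c("cutpoint", "snb"))
  g <- glance(sc)
  expect_equal(g$snb_max, sc$snb_max)
  expect_s3_class(autoplot(sc), "ggplot")
})
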