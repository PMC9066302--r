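test_that("the line of additivity interpolates the monocultures", {
  expect_equal(additive_expectation(1, 0.8, 0.4), 0.8)
  expect_equal(additive_expectation(0, 0.8, 0.4), 0.4)
  expect_equal(additive_expectation(0.5, 0.4, 0.6), 0.5)
  expect_equal(additive_expectation(0.25, 0.8, 0.4), 0.5)
  expect_error(additive_expectation(1.2, 1, 1), "\\[0, 1\\]")
})

test_that("relative density recovers the printed pair-wise summaries", {
  # 50-50 relative OD equals the co-culture mean minus the monoculture mean
  expect_equal(relative_density(0.5417, 0.5, 0.4627, 0.4627), 0.0790)
  expect_equal(relative_density(0.6073, 0.5, 0.37035, 0.37035), 0.23695)
  expect_equal(relative_density(0.5, 0.3, 0.6, 0.4), 0.5 - (0.3 * 0.6 + 0.7 * 0.4))
  # additive co-culture is neutral; endpoints are exactly zero
  expect_equal(relative_density(0.5, 0.5, 0.6, 0.4), 0)
  expect_equal(relative_density(0.6, 1, 0.6, 0.4), 0)
  expect_equal(relative_density(0.4, 0, 0.6, 0.4), 0)
})

test_that("frequency profiles validate their structure", {
  expect_error(frequency_profile(c(0, 0.5), c(1, 2, 3)), "equal length")
  expect_error(frequency_profile(c(0.2, 0.5, 0.8), c(1, 2, 3)), "endpoints")
  expect_error(frequency_profile(c(0, 1.5, 1), c(1, 2, 3)), "\\[0, 1\\]")
  prof <- frequency_profile(c(0, 0.5, 1, 0, 0.5, 1), c(1, 3, 2, 1.2, 3.2, 1.8),
                            replicate = rep(1:2, each = 3))
  expect_equal(attr(prof, "mono_focal"), 1.9)
  expect_equal(attr(prof, "mono_partner"), 1.1)
})

test_that("quadratic fits recover noiseless generating coefficients exactly", {
  x <- seq(0, 1, by = 0.1)
  # raw response generated by the through-origin model
  prof <- frequency_profile(x, 2 * x^2 + 3 * x)
  fit <- fit_interaction_curve(prof, response = "raw")
  expect_equal(fit$alpha, 2, tolerance = 1e-10)
  expect_equal(fit$beta_fit, 3, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
  # delta response: a model-family curve vanishing at both endpoints
  prof2 <- frequency_profile(x, additive_expectation(x, 0.6, 0.4) +
                               1.5 * (x^2 - x))
  fit2 <- fit_interaction_curve(prof2)
  expect_equal(fit2$alpha, 1.5, tolerance = 1e-10)
  expect_equal(fit2$beta_fit, -1.5, tolerance = 1e-10)
  expect_equal(fit2$r_squared, 1)
  # identically zero response fits flat with alpha = beta = 0
  prof0 <- frequency_profile(x, additive_expectation(x, 0.5, 0.3))
  fit0 <- fit_interaction_curve(prof0)
  expect_equal(fit0$alpha, 0, tolerance = 1e-10)
  expect_equal(fit0$beta_fit, 0, tolerance = 1e-10)
  expect_error(fit_interaction_curve(
    frequency_profile(c(0, 1), c(1, 2))), "3 distinct")
})

test_that("noisy quadratic fits stay within two standard errors", {
  set.seed(1)
  x <- rep(seq(0, 1, by = 0.1), each = 4)
  y <- 0.4 * x^2 + 0.2 * x + stats::rnorm(length(x), 0, 0.02)
  fit <- stats::lm(y ~ 0 + I(x^2) + x)
  se <- sqrt(diag(stats::vcov(fit)))
  prof <- frequency_profile(x, y, replicate = rep(1:4, times = 11))
  got <- fit_interaction_curve(prof, response = "raw")
  expect_lt(abs(got$alpha - 0.4), 2 * se[1])
  expect_lt(abs(got$beta_fit - 0.2), 2 * se[2])
  expect_gt(got$r_squared, 0.9)
})

test_that("optimal initial frequency picks the argmax, ties to the left", {
  x <- seq(0, 1, by = 0.1)
  concave <- frequency_profile(x, 1 - (x - 0.7)^2)
  expect_equal(as.numeric(optimal_initial_frequency(concave)), 0.7)
  rising <- frequency_profile(x, x)
  expect_equal(as.numeric(optimal_initial_frequency(rising)), 1.0)
  tied <- frequency_profile(c(0, 0.4, 0.6, 1), c(0, 5, 5, 0))
  expect_equal(as.numeric(optimal_initial_frequency(tied)), 0.4)
  reps <- frequency_profile(rep(c(0, 0.5, 1), 2), c(1, 4, 1, 1, 6, 1),
                            replicate = rep(1:2, each = 3))
  expect_equal(attr(optimal_initial_frequency(reps), "dispersion"),
               stats::sd(c(4, 6)))
})

test_that("fluorescence composition inverts the two-channel readout", {
  blank <- c(cfp = 50, mcherry = 50)
  mono_max <- c(cfp = 1000, mcherry = 800)
  pure <- abundance_from_fluorescence(1050, 50, blank, mono_max)
  expect_equal(pure$cfp_fraction, 1)
  expect_equal(pure$mcherry_fraction, 0)
  even <- abundance_from_fluorescence(550, 450, blank, mono_max)
  expect_equal(even$cfp_fraction, 0.5)
  expect_error(abundance_from_fluorescence(50, 50, blank, mono_max),
               "both channels at blank")
  expect_error(abundance_from_fluorescence(10, 500, blank, mono_max),
               "blanks")
  # known 70:30 composition with 2% multiplicative noise recovers within 0.05
  set.seed(48)
  true_frac <- 0.7
  cfp <- blank[["cfp"]] + mono_max[["cfp"]] * true_frac *
    exp(stats::rnorm(50, 0, 0.02))
  mch <- blank[["mcherry"]] + mono_max[["mcherry"]] * (1 - true_frac) *
    exp(stats::rnorm(50, 0, 0.02))
  est <- abundance_from_fluorescence(cfp, mch, blank, mono_max)
  expect_true(all(abs(est$cfp_fraction - true_frac) < 0.05))
})

test_that("interaction classification follows the better/worse rule", {
  expect_equal(classify_interaction(0.2, 0.2, 0.1, 0.1), "mutualism")
  expect_equal(classify_interaction(0.2, 0.05, 0.1, 0.1), "parasitism")
  expect_equal(classify_interaction(0.05, 0.08, 0.1, 0.1), "competition")
  # equal performance is not strictly worse: parasitism bucket
  expect_equal(classify_interaction(0.2, 0.1, 0.1, 0.1), "parasitism")
  expect_equal(classify_interaction(0.1, 0.1, 0.1, 0.1), "parasitism")
  expect_error(classify_interaction(-0.1, 0.1, 0.1, 0.1), "nonnegative")
  # invariant under strain-label exchange: mutualism and competition are
  # fixed points, parasitism maps to parasitism
  set.seed(49)
  for (i in 1:30) {
    v <- stats::runif(4, 0, 1)
    a <- classify_interaction(v[1], v[2], v[3], v[4])
    b <- classify_interaction(v[2], v[1], v[4], v[3])
    expect_identical(a, b)
  }
  # vectorised over cells
  expect_equal(classify_interaction(c(0.2, 0.05), c(0.2, 0.04),
                                    c(0.1, 0.1), c(0.1, 0.1)),
               c("mutualism", "competition"))
})

test_that("simulated frequency profiles are concave and skewed by the k2 asymmetry", {
  surf <- default_surface()
  prof <- simulate_frequency_profile(seq(0, 1, by = 0.1), surfaces = surf)
  expect_s3_class(prof, "frequency_profile")
  # mutualistic regime: interior co-cultures beat both monocultures
  opt <- as.numeric(optimal_initial_frequency(prof))
  expect_true(opt > 0 && opt < 1)
  expect_gt(max(prof$density), attr(prof, "mono_focal"))
  expect_gt(max(prof$density), attr(prof, "mono_partner"))
  # the asymmetric amino-acid conversions skew the profile towards a
  # B_x majority (B_y converts its supply more efficiently)
  expect_gt(prof$density[which.min(abs(prof$fraction - 0.6))],
            prof$density[which.min(abs(prof$fraction - 0.4))])
})
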