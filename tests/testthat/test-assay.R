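test_that("doubling time recovers closed-form exponential growth", {
  t <- seq(0, 300, by = 10)
  g <- data.frame(time = t, od600 = 0.05 * 2^(t / 30))
  expect_equal(doubling_time(g), 30, tolerance = 1e-6)
  ## scale invariance: OD units cancel in the log-slope
  g2 <- g; g2$od600 <- g2$od600 * 7.3
  expect_equal(doubling_time(g2), doubling_time(g), tolerance = 1e-9)
})

test_that("flat or declining curves raise an error", {
  g <- data.frame(time = seq(0, 100, 10), od600 = rep(0.5, 11))
  expect_error(doubling_time(g), "positive growth")
  g$od600 <- rep(0.001, 11)
  expect_error(doubling_time(g), "OD floor")
})

test_that("doubling time survives moderate measurement noise", {
  for (dt in c(20, 40, 60)) {
    for (seed in 1:3) {
      g <- growth_curve_generator(doubling_time = dt, capacity = 2.5,
                                  noise_sd = 0.02, seed = seed)
      expect_lt(abs(doubling_time(g) - dt) / dt, 0.05,
                label = sprintf("DT=%g seed=%d relative error", dt, seed))
    }
  }
})

test_that("max OD behaves on monotone, logistic and constant curves", {
  mono <- data.frame(time = 1:5, od600 = c(0.1, 0.2, 0.4, 0.8, 1.6))
  expect_identical(max_od(mono), 1.6)
  expect_identical(max_od(data.frame(od600 = rep(0.7, 4))), 0.7)
  g <- growth_curve_generator(doubling_time = 40, capacity = 2.5,
                              noise_sd = 0, horizon = 2000, seed = 1L)
  expect_equal(max_od(g, smooth = 5L), 2.5, tolerance = 1e-2)
})

test_that("percent change is plain relative change", {
  expect_equal(pct_change(30, 46.2), 54, tolerance = 1e-9)
  expect_identical(pct_change(17, 17), 0)
  expect_identical(pct_change(50, 25), -50)
  expect_error(pct_change(0, 1), "positive")
})

test_that("segmented blot calibration interpolates and extrapolates", {
  ## perfectly linear response: intensity = 3 * ng
  std <- data.frame(amount = c(1, 10, 50, 100), intensity = 3 * c(1, 10, 50, 100))
  cal <- calibration_curve(std)
  expect_equal(quantify_blot(cal, 30), 10, tolerance = 1e-9)
  expect_equal(quantify_blot(cal, 3 * 75), 75, tolerance = 1e-9)
  ## brightest sample beyond the top standard, as quantified in the study
  expect_equal(quantify_blot(cal, 1.36 * 300), 136, tolerance = 1e-9)
  ## below the 1 ng standard: blank-anchored line
  expect_equal(quantify_blot(cal, 1.5), 0.5, tolerance = 1e-9)
  expect_error(quantify_blot(cal, -1), "nonnegative")
})

test_that("blot quantification is monotone for monotone standards", {
  std <- data.frame(amount = c(1, 10, 50, 100),
                    intensity = c(2, 35, 160, 300))  # sublinear low range
  cal <- calibration_curve(std)
  xs <- seq(0, 400, by = 5)
  ys <- vapply(xs, function(i) quantify_blot(cal, i), numeric(1L))
  expect_true(all(diff(ys) >= -1e-9))
})

test_that("conjugation percent transfer counts patched colonies", {
  expect_identical(conjugation_pct(86), 100)
  expect_identical(conjugation_pct(43), 50)
  expect_identical(conjugation_pct(0), 0)
  expect_error(conjugation_pct(87), "n_picked")
})

test_that("relative titer handles dilution-corrected plaque counts", {
  expect_identical(relative_titer(1e8, 1e8), 1)
  ## a 10-fold dilution with 10-fold fewer plaques is the same titer
  expect_identical(pfu_per_ml(30, dilution = 1e6),
                   pfu_per_ml(3, dilution = 1e7))
  expect_identical(relative_titer(pfu_per_ml(0, 1e6), 1e8), 0)
  expect_error(relative_titer(1, 0), "positive")
})
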