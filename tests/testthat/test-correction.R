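test_that("decay factor zeroes out at the grid start and shrinks with pilot size", {
  expect_equal(decay_factor(20, 20), 1)
  expect_equal(decay_factor(100, 20), 0.5234901, tolerance = 1e-6)
  expect_equal(decay_factor(40, 20), 0.8418861, tolerance = 1e-6)
  f <- decay_factor(seq(20, 500, 20), 20)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(diff(f) < 0))
  expect_error(decay_factor(10, 20), "at least")

  expect_equal(apply_decay(100, 20, 20), 100)
  expect_equal(apply_decay(200, 100, 20), 200 * decay_factor(100, 20))
})

test_that("the nine-term regression reproduces published worked corrections", {
  co <- correction_coefficients()
  expect_equal(regression_correction(45, 29, 0.14, 80, co), 39.63,
               tolerance = 0.005)
  expect_equal(regression_correction(125, 33, 0.0809, 95, co), 107.09,
               tolerance = 0.001)
  # alternate pooled-decile coefficient set is selectable and differs
  alt <- correction_coefficients("all_deciles")
  expect_false(isTRUE(all.equal(regression_correction(45, 29, 0.14, 80, alt),
                                regression_correction(45, 29, 0.14, 80, co))))
  expect_error(regression_correction(45, 29, 0, 80), "positive")
})

test_that("loss adjustment divides by retention and rounds up", {
  expect_equal(loss_adjust(41.2, 1), 42)
  expect_equal(loss_adjust(50, 0.8), 63)
  expect_equal(loss_adjust(39.63, 0.93), 43)  # 42.61 rounded up
  expect_true(loss_adjust(37.4, 1) >= 37.4)
  expect_gte(loss_adjust(40, 0.7), loss_adjust(40, 0.9))
  expect_error(loss_adjust(50, 0), "retention")
})

test_that("the plan assembles per-level corrections with min/max designation", {
  summ <- data.frame(sample_size = c(20, 40, 45, 50, 55),
                     percent_below = c(0.50, 0.70, 0.85, 0.90, 0.95))
  plan <- calculate_correction(summ, pilot_n = 29, prop_var = 0.14,
                               retention = 1, se_cutoff = 0.18,
                               nominal_power = TRUE)
  expect_equal(plan$levels$projected_n, c(45, 45, 50, 55))
  # nominal powers reproduce the published concreteness corrections
  expect_equal(plan$levels$corrected_n, c(39.63, 39.29, 45.30, 51.21),
               tolerance = 0.005)
  expect_equal(plan$minimum_n, plan$levels$final_n[1])
  expect_equal(plan$maximum_n, plan$levels$final_n[4])
  expect_true(all(diff(plan$levels$final_n[2:4]) >= 0))
  expect_equal(plan$levels$final_n, ceiling(plan$levels$corrected_n))

  # achieved power is the default regression input
  plan2 <- calculate_correction(summ, 29, 0.14, se_cutoff = 0.18)
  expect_equal(plan2$levels$power_used, c(85, 85, 90, 95))

  # unreached levels are marked and excluded from min/max designation
  plan3 <- calculate_correction(summ[1:4, ], 29, 0.14,
                                power_levels = c(80, 90, 95))
  expect_false(plan3$levels$reached[3])
  expect_equal(plan3$maximum_n,
               plan3$levels$final_n[plan3$levels$power_level == 90])

  # retention inflates every final n
  plan4 <- calculate_correction(summ, 29, 0.14, retention = 0.8,
                                nominal_power = TRUE)
  expect_equal(plan4$levels$final_n,
               as.integer(ceiling(plan$levels$corrected_n / 0.8)))
})

test_that("sub-grid corrected sizes are floored at the grid start", {
  summ <- data.frame(sample_size = c(20, 25), percent_below = c(0.9, 0.99))
  # tiny projected n and high pilot n drive the regression below the grid
  expect_warning(
    plan <- calculate_correction(summ, pilot_n = 300, prop_var = 0.01,
                                 power_levels = 80),
    "floored")
  expect_equal(plan$levels$corrected_n, 20)
})
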