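test_that("per-item SEs use the sample SD over sqrt(n)", {
  df <- data.frame(
    participant = rep(paste0("p", 1:5), 3),
    item = rep(c("const", "ramp", "ramp2"), each = 5),
    score = c(rep(3, 5), 1:5, c(5, 3, 1, 4, 2))
  )
  prec <- item_precision(df)
  expect_equal(prec$sd[prec$item == "const"], 0)
  expect_equal(prec$se[prec$item == "const"], 0)
  # hand-computed n-1 SD oracle: sd(1..5) = sqrt(2.5)
  expect_equal(prec$sd[prec$item == "ramp"], sqrt(2.5))
  expect_equal(prec$se[prec$item == "ramp"], sqrt(2.5) / sqrt(5))
  expect_equal(round(prec$sd[prec$item == "ramp"], 4), 1.5811)
  expect_equal(round(prec$se[prec$item == "ramp"], 4), 0.7071)
  # permutation invariance: identical multisets give identical SEs
  expect_equal(prec$se[prec$item == "ramp"], prec$se[prec$item == "ramp2"])
})

test_that("decile cutoff interpolates order statistics at h = (n-1)q + 1", {
  expect_equal(decile_cutoff(rep(2.5, 6), 0.4), 2.5)
  expect_equal(decile_cutoff(1:10, 0.4), 4.6)
  expect_equal(decile_cutoff(c(1, 2, 3), 0.5), 2)
  expect_error(decile_cutoff(1, 0.4), "at least 2")
  expect_error(decile_cutoff(1:5, 0), "between 0 and 1")

  # property: matches the independent interpolation oracle on random input
  set.seed(41)
  for (rep in 1:25) {
    x <- rexp(sample(3:40, 1))
    q <- runif(1, 0.05, 0.95)
    expect_equal(decile_cutoff(x, q), quantile_oracle(x, q))
  }
  # monotone in the decile and equivariant under positive scaling
  x <- rexp(15)
  qs <- seq(0.1, 0.9, 0.1)
  cuts <- vapply(qs, function(q) decile_cutoff(x, q), numeric(1))
  expect_true(all(diff(cuts) >= 0))
  expect_equal(decile_cutoff(3.7 * x, 0.4), 3.7 * decile_cutoff(x, 0.4))
})

test_that("proportion of possible variance divides by half the range", {
  expect_equal(proportion_of_variance(0.28, scale_spec(1, 5)), 0.14)
  expect_equal(round(proportion_of_variance(140.83, scale_spec(0, 3480)), 2),
               0.08)
  expect_equal(proportion_of_variance(0, scale_spec(1, 7)), 0)
  # scale-free: multiplying scores and bounds by c leaves it unchanged
  expect_equal(proportion_of_variance(0.28 * 10, scale_spec(10, 50)),
               proportion_of_variance(0.28, scale_spec(1, 5)))
})

test_that("cutoff bundle brackets order statistics and rounds pilot n up", {
  pop <- simulate_population(population_preset("likert", "medium",
                                               n_obs = 300), seed = 42)
  pilot <- draw_pilot(pop, 30, seed = 43)
  res <- calculate_cutoff(pilot, scale_spec(1, 7))
  ses <- sort(res$per_item$se)
  # h = 29 * 0.4 + 1 = 12.6: cutoff lies between the 12th and 13th order stats
  expect_gte(res$se_cutoff, ses[12])
  expect_lte(res$se_cutoff, ses[13])
  expect_equal(res$pilot_n, 30)
  expect_equal(res$prop_var, res$sd_item_sd / 3)

  # identical items: cutoff equals the common SE, no heterogeneity
  same <- data.frame(participant = rep(paste0("p", 1:4), 3),
                     item = rep(c("a", "b", "c"), each = 4),
                     score = rep(c(1, 3, 5, 7), 3))
  res2 <- calculate_cutoff(same, scale_spec(1, 7))
  expect_equal(res2$se_cutoff, sd(c(1, 3, 5, 7)) / 2)
  expect_equal(res2$prop_var, 0)

  # mixed per-item n: pilot_n is the ceiling of the mean (28.33 -> 29)
  mix <- data.frame(
    participant = unlist(lapply(c(28, 28, 31), seq_len)),
    item = rep(c("a", "b", "c"), times = c(28, 28, 31)),
    score = rnorm(87)
  )
  expect_equal(calculate_cutoff(mix, scale_spec(-5, 5))$pilot_n, 29)
})

test_that("inferred scales trigger a warning and match the data range", {
  pilot <- toy_pilot()
  expect_warning(res <- calculate_cutoff(pilot), "inferred")
  expect_equal(res$scale$minimum, min(pilot$score))
})

test_that("stopping flags compare item SEs strictly against the cutoff", {
  df <- data.frame(participant = rep(paste0("p", 1:4), 3),
                   item = rep(c("tight", "loose", "flat"), each = 4),
                   score = c(5, 5.1, 4.9, 5, 1, 9, 2, 8, rep(3, 4)))
  prec <- item_precision(df)
  cut <- 0.5
  res <- check_stop(df, cut)
  expect_equal(res$per_item$stopped, prec$se < cut)
  expect_false(res$all_stopped)
  expect_true(check_stop(df, 100)$all_stopped)
  # a cutoff below the smallest attainable SE stops nothing
  none <- check_stop(df[df$item != "flat", ], 1e-6)
  expect_false(any(none$per_item$stopped))
})

test_that("heterogeneity of item SDs rises with sigma_sigma", {
  mean_sdsd <- vapply(c("small", "medium", "large"), function(h) {
    mean(vapply(1:8, function(r) {
      pop <- simulate_population(population_preset("likert", h,
                                                   n_obs = 500),
                                 seed = 4400 + r)
      sd(item_precision(pop)$sd)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_sdsd) > 0))
})
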