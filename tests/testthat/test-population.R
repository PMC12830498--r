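test_that("simulated scores respect scale bounds and integrality", {
  for (sc in c("likert", "percent", "milliseconds")) {
    cfg <- population_preset(sc, "large", "ceiling", n_obs = 200)
    pop <- simulate_population(cfg, seed = 21)
    expect_true(all(pop$score >= cfg$scale$minimum))
    expect_true(all(pop$score <= cfg$scale$maximum))
    expect_true(all(pop$score == round(pop$score)))
  }
  pop <- simulate_population(population_preset("likert", "small"), seed = 22)
  expect_equal(length(unique(pop$item)), 30)
  expect_equal(nrow(pop), 30 * 1000)
})

test_that("degenerate variance collapses every score onto the rounded mean", {
  cfg <- population_config(n_items = 5, n_obs = 50, mu = 4.3, sigma_mu = 0,
                           sigma = 1e-9, sigma_sigma = 0,
                           scale = scale_spec(1, 7))
  pop <- simulate_population(cfg, seed = 23)
  expect_true(all(pop$score == 4))
})

test_that("item means and SDs recover their drawing distributions", {
  # grand mean of item means within 3 Monte Carlo SEs of mu
  cfg <- population_preset("likert", "small", n_obs = 10000)
  pop <- simulate_population(cfg, seed = 24)
  prec <- item_precision(pop)
  mc_se <- cfg$sigma_mu / sqrt(cfg$n_items)
  expect_lt(abs(mean(prec$mean) - cfg$mu), 3 * mc_se)

  # empirical SD of item SDs tracks sigma_sigma when clamping is mild
  cfg2 <- population_preset("milliseconds", "small", n_items = 150,
                            n_obs = 1000)
  pop2 <- simulate_population(cfg2, seed = 25)
  prec2 <- item_precision(pop2)
  expect_equal(sd(prec2$sd), cfg2$sigma_sigma, tolerance = 0.25)
})

test_that("ceiling configurations pile up at the top and skew left", {
  cfg <- population_preset("likert", "small", "ceiling", n_obs = 5000)
  pop <- simulate_population(cfg, seed = 26)
  prec <- item_precision(pop)
  expect_lt(mean(prec$mean), cfg$mu)  # clamping pulls below the drawing mean
  expect_gt(mean(pop$score == 7), 0.2)
})

test_that("bimodal items mix a ceiling and a floor component", {
  cfg <- population_config(n_items = 1, n_obs = 10000, mu = 4,
                           sigma_mu = 0.25, sigma = 0.3, sigma_sigma = 0.01,
                           scale = scale_spec(1, 7), bimodal_fraction = 1,
                           mu_ceiling = 6)
  set.seed(27)
  x <- make_bimodal_item(cfg)
  # tiny SDs concentrate scores at the two modes (6 and 2)
  expect_gt(mean(x == 6), 0.4)
  expect_gt(mean(x == 2), 0.4)
  # mixture mean sits at the midpoint of the modes within 3 SEs
  mix_se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 4), 3 * mix_se)

  # zero bimodal fraction reproduces the plain generator draw for draw
  cfg0 <- population_preset("likert", "small", n_obs = 100)
  a <- simulate_population(cfg0, seed = 28)
  cfg0$bimodal_fraction <- 0
  b <- simulate_population(cfg0, seed = 28)
  expect_identical(a, b)

  # odd n_obs gives the larger half to the ceiling component
  cfg_odd <- cfg
  cfg_odd$n_obs <- 101L
  set.seed(29)
  x_odd <- make_bimodal_item(cfg_odd)
  expect_equal(length(x_odd), 101)
  expect_gt(sum(x_odd >= 4), sum(x_odd < 4))
})

test_that("excessive SD heterogeneity fails after bounded redraws", {
  cfg <- population_config(n_items = 5, n_obs = 10, mu = 4, sigma_mu = 0,
                           sigma = 0.1, sigma_sigma = 100,
                           scale = scale_spec(1, 7))
  expect_error(simulate_population(cfg, seed = 30), "sigma_sigma")
})

test_that("pilot draws resample each item with replacement, reproducibly", {
  const <- data.frame(participant = paste0("p", 1:5),
                      item = "only", score = 3)
  pil <- draw_pilot(const, 20, seed = 31)
  expect_equal(nrow(pil), 20)
  expect_true(all(pil$score == 3))

  pop <- simulate_population(population_preset("likert", "small",
                                               n_obs = 500), seed = 32)
  expect_identical(draw_pilot(pop, 25, seed = 33),
                   draw_pilot(pop, 25, seed = 33))
  expect_error(draw_pilot(pop, 1), "at least 2")

  # large resamples concentrate on the population item means
  big <- draw_pilot(pop, 5000, seed = 34)
  pm <- item_precision(pop)
  bm <- item_precision(big)
  boot_se <- pm$sd / sqrt(5000)
  expect_lt(max(abs(bm$mean - pm$mean) / boot_se), 4.5)
})
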