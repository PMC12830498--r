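#' Define a factorial validation grid
#'
#' The harness replays the planning procedure across a factorial design of
#' population conditions (scale x heterogeneity x distribution shape) and
#' pilot sample sizes, with many simulated "researchers" each drawing their
#' own pilot from a shared population. Defaults are scaled down from the
#' full benchmark design (100 researchers, grid to 2000) so a complete
#' evaluation runs on a laptop; the full design is reachable by arguments.
#'
#' @param scales Subset of `c("likert", "percent", "milliseconds")`.
#' @param heterogeneity Subset of `c("small", "medium", "large")`.
#' @param shapes Subset of `c("symmetric", "ceiling")`.
#' @param pilot_sizes Pilot sample sizes to evaluate.
#' @param n_researchers Independent pilot draws per condition.
#' @param grid A [sample_grid()] for the researcher bootstrap.
#' @param levels Target fractions of precise items. Default
#'   `c(0.8, 0.85, 0.9, 0.95)`.
#' @param n_items,n_obs Population dimensions.
#' @param seed Master seed; every sub-draw derives from it.
#' @return A list of class `condition_grid`.
#' @export
condition_grid <- function(scales = c("likert", "percent", "milliseconds"),
                           heterogeneity = c("small", "medium", "large"),
                           shapes = c("symmetric", "ceiling"),
                           pilot_sizes = seq(20, 40, 10),
                           n_researchers = 20,
                           grid = sample_grid(20, 300, 20, nsim = 50),
                           levels = c(0.8, 0.85, 0.9, 0.95),
                           n_items = 30, n_obs = 1000, seed = NULL) {
  scales <- match.arg(scales, several.ok = TRUE)
  heterogeneity <- match.arg(heterogeneity, several.ok = TRUE)
  shapes <- match.arg(shapes, c("symmetric", "ceiling", "floor"),
                      several.ok = TRUE)
  stopifnot(length(pilot_sizes) >= 1, n_researchers >= 1,
            inherits(grid, "sample_grid"))
  structure(list(scales = scales, heterogeneity = heterogeneity,
                 shapes = shapes, pilot_sizes = pilot_sizes,
                 n_researchers = as.integer(n_researchers), grid = grid,
                 levels = levels, n_items = n_items, n_obs = n_obs,
                 seed = seed),
            class = "condition_grid")
}

# derive reproducible 31-bit sub-seeds from a master seed
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  set.seed(seed)
  as.list(sample.int(.Machine$integer.max - 1L, n))
}

#' Run the planning procedure once under a simulated condition
#'
#' Draws a population, samples one researcher's pilot from it, computes the
#' cutoff, bootstraps the percent-below-cutoff curve, and reports per power
#' level the projected sample size together with its decay-corrected value
#' (the harness's ground truth) and the regression-corrected value (what a
#' real researcher would compute).
#'
#' @param config A [population_config()] or [population_preset()].
#' @param pilot_size Researcher pilot sample size.
#' @param grid A [sample_grid()].
#' @param levels Target fractions of precise items.
#' @param decile Cutoff decile. Default 0.4.
#' @param seed Optional master seed for the population, pilot, and
#'   bootstrap draws.
#' @return A data frame with one row per level: `level`, `projected_n`,
#'   `achieved`, `decay_n`, `regression_n`, `reached`, plus the pilot
#'   cutoff diagnostics `se_cutoff`, `prop_var`.
#' @export
run_condition <- function(config, pilot_size, grid = sample_grid(20, 300, 20,
                                                                 nsim = 50),
                          levels = c(0.8, 0.85, 0.9, 0.95), decile = 0.4,
                          seed = NULL) {
  seeds <- derive_seeds(seed, 3)
  pop <- simulate_population(config, seed = seeds[[1]])
  pilot <- draw_pilot(pop, pilot_size, seed = seeds[[2]])
  cutoff <- calculate_cutoff(pilot, scale = config$scale, decile = decile)
  if (cutoff$se_cutoff <= 0) {
    # every item already at zero SE: any simulated size suffices, so the
    # smallest one is the projection at every level
    summary <- data.frame(sample_size = grid$sizes,
                          percent_below = rep(1, length(grid$sizes)))
  } else {
    ses <- simulate_samples(pilot, grid, seed = seeds[[3]])
    summary <- calculate_proportion(ses, cutoff$se_cutoff)
  }
  rows <- lapply(levels, function(lv) {
    proj <- projected_n(summary, lv)
    if (!proj$reached) {
      return(data.frame(level = lv, projected_n = NA_integer_,
                        achieved = NA_real_, decay_n = NA_real_,
                        regression_n = NA_real_, reached = FALSE))
    }
    data.frame(
      level = lv, projected_n = proj$sample_size, achieved = proj$achieved,
      decay_n = apply_decay(proj$sample_size, pilot_size, grid$start),
      regression_n = if (cutoff$prop_var > 0) {
        regression_correction(proj$sample_size, cutoff$pilot_n,
                              cutoff$prop_var, 100 * proj$achieved)
      } else NA_real_,  # log2 term undefined for perfectly homogeneous items
      reached = TRUE
    )
  })
  out <- do.call(rbind, rows)
  out$se_cutoff <- cutoff$se_cutoff
  out$prop_var <- cutoff$prop_var
  out
}

#' Stability and bias of recommendations across pilot sizes
#'
#' For each condition and pilot size, `n_researchers` simulated researchers
#' draw independent pilots from one shared population and run the bootstrap
#' projection. Three statistics summarise how trustworthy small pilots are:
#'
#' * `sd_recommended_n` — SD over researchers of the decay-corrected
#'   recommended N at each level (instability: how differently two
#'   researchers with similar pilots would be advised);
#' * `rel_se_bias` — mean over items and researchers of
#'   (estimated SE - true SE) / true SE, where the true SE is the
#'   population item SD at the same pilot n;
#' * `rel_cutoff_bias` — (pilot-derived cutoff - population cutoff) /
#'   population cutoff, the population cutoff being the chosen decile of
#'   the population item SEs at the same pilot n.
#'
#' @param conditions A [condition_grid()].
#' @param decile Cutoff decile. Default 0.4.
#' @return A data frame with one row per scale x heterogeneity x shape x
#'   pilot size x level, carrying the three statistics and
#'   `mean_recommended_n`.
#' @export
evaluate_pilot_sizes <- function(conditions = condition_grid(),
                                 decile = 0.4) {
  stopifnot(inherits(conditions, "condition_grid"))
  combos <- expand.grid(scale = conditions$scales,
                        heterogeneity = conditions$heterogeneity,
                        shape = conditions$shapes,
                        stringsAsFactors = FALSE)
  seeds <- derive_seeds(conditions$seed, nrow(combos))
  out <- list()
  for (ci in seq_len(nrow(combos))) {
    cfg <- population_preset(combos$scale[ci], combos$heterogeneity[ci],
                             combos$shape[ci], n_items = conditions$n_items,
                             n_obs = conditions$n_obs)
    sub <- derive_seeds(seeds[[ci]],
                        1 + length(conditions$pilot_sizes))
    pop <- simulate_population(cfg, seed = sub[[1]])
    pop_prec <- item_precision(pop)
    for (pi in seq_along(conditions$pilot_sizes)) {
      np <- conditions$pilot_sizes[pi]
      true_se <- pop_prec$sd / sqrt(np)
      pop_cutoff <- decile_cutoff(true_se, decile)
      rseeds <- derive_seeds(sub[[1 + pi]], conditions$n_researchers)
      rec <- matrix(NA_real_, conditions$n_researchers,
                    length(conditions$levels))
      se_bias <- cut_bias <- numeric(conditions$n_researchers)
      for (r in seq_len(conditions$n_researchers)) {
        rs <- derive_seeds(rseeds[[r]], 2)
        pilot <- draw_pilot(pop, np, seed = rs[[1]])
        prec <- item_precision(pilot)
        est_se <- prec$se[match(pop_prec$item, prec$item)]
        se_bias[r] <- mean((est_se - true_se) / true_se)
        pilot_cutoff <- decile_cutoff(prec$se, decile)
        cut_bias[r] <- (pilot_cutoff - pop_cutoff) / pop_cutoff
        ses <- simulate_samples(pilot, conditions$grid, seed = rs[[2]])
        summary <- calculate_proportion(ses, pilot_cutoff)
        for (li in seq_along(conditions$levels)) {
          proj <- projected_n(summary, conditions$levels[li])
          if (proj$reached) {
            rec[r, li] <- apply_decay(proj$sample_size, np,
                                      conditions$grid$start)
          }
        }
      }
      out[[length(out) + 1]] <- data.frame(
        scale = combos$scale[ci], heterogeneity = combos$heterogeneity[ci],
        shape = combos$shape[ci], pilot_size = np,
        level = conditions$levels,
        mean_recommended_n = colMeans(rec, na.rm = TRUE),
        sd_recommended_n = apply(rec, 2, stats::sd, na.rm = TRUE),
        rel_se_bias = mean(se_bias), rel_cutoff_bias = mean(cut_bias),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Recommended sample size as the bimodal item fraction varies
#'
#' Sweeps the proportion of bimodal items (ceiling + floor mixtures) in a
#' Likert-type population and records the recommended N at each target
#' level, averaged over replicates. A rising-then-falling pattern is
#' expected: a few bimodal items inflate the heterogeneity of item SEs (so
#' N rises), while an all-bimodal set is homogeneous again (so N falls).
#'
#' @param fractions Bimodal fractions to sweep. Default `seq(0, 1, 0.1)`.
#' @param config Base population; default Likert, small heterogeneity,
#'   symmetric.
#' @param pilot_size Pilot draw per replicate. Default 30.
#' @param grid A [sample_grid()].
#' @param levels Target fractions of precise items.
#' @param n_rep Replicates per fraction. Default 10.
#' @param decile Cutoff decile.
#' @param seed Master seed.
#' @return Data frame: one row per fraction x level with
#'   `mean_projected_n`, `mean_decay_n`, and `mean_se_sd` (the SD across
#'   items of pilot SEs, the heterogeneity that drives the pattern).
#' @export
bimodal_sweep <- function(fractions = seq(0, 1, 0.1),
                          config = population_preset("likert", "small"),
                          pilot_size = 30,
                          grid = sample_grid(20, 300, 20, nsim = 50),
                          levels = c(0.8, 0.85, 0.9, 0.95),
                          n_rep = 10, decile = 0.4, seed = NULL) {
  stopifnot(all(fractions >= 0 & fractions <= 1), n_rep >= 1)
  seeds <- derive_seeds(seed, length(fractions))
  out <- list()
  for (fi in seq_along(fractions)) {
    cfg <- config
    cfg$bimodal_fraction <- fractions[fi]
    rseeds <- derive_seeds(seeds[[fi]], n_rep)
    proj <- dec <- matrix(NA_real_, n_rep, length(levels))
    se_sd <- numeric(n_rep)
    for (r in seq_len(n_rep)) {
      rs <- derive_seeds(rseeds[[r]], 3)
      pop <- simulate_population(cfg, seed = rs[[1]])
      pilot <- draw_pilot(pop, pilot_size, seed = rs[[2]])
      cutoff <- calculate_cutoff(pilot, scale = cfg$scale, decile = decile)
      se_sd[r] <- stats::sd(cutoff$per_item$se)
      ses <- simulate_samples(pilot, grid, seed = rs[[3]])
      summary <- calculate_proportion(ses, cutoff$se_cutoff)
      for (li in seq_along(levels)) {
        p <- projected_n(summary, levels[li])
        if (p$reached) {
          proj[r, li] <- p$sample_size
          dec[r, li] <- apply_decay(p$sample_size, pilot_size, grid$start)
        }
      }
    }
    out[[fi]] <- data.frame(
      fraction = fractions[fi], level = levels,
      mean_projected_n = colMeans(proj, na.rm = TRUE),
      mean_decay_n = colMeans(dec, na.rm = TRUE),
      mean_se_sd = mean(se_sd)
    )
  }
  do.call(rbind, out)
}

#' Average proportion of possible variance per scale
#'
#' Regenerates benchmark populations (symmetric and ceiling shapes at every
#' requested heterogeneity level) and averages the proportion of possible
#' variance — SD of item SDs over half the scale range — across conditions
#' and replicates for each scale. Under the benchmark parameterisation the
#' percent scale carries the most relative heterogeneity, then Likert, then
#' milliseconds.
#'
#' @param scales Scales to summarise.
#' @param heterogeneity Heterogeneity levels to include.
#' @param shapes Distribution shapes to include.
#' @param n_rep Replicates per condition. Default 50.
#' @param n_items,n_obs Population dimensions. Defaults 30 x 1000.
#' @param seed Master seed.
#' @return A list with `by_scale` (named mean proportions) and `detail`
#'   (one row per condition x replicate).
#' @export
prop_var_by_scale <- function(scales = c("likert", "percent", "milliseconds"),
                              heterogeneity = c("small", "medium", "large"),
                              shapes = c("symmetric", "ceiling"),
                              n_rep = 50, n_items = 30, n_obs = 1000,
                              seed = NULL) {
  combos <- expand.grid(scale = scales, heterogeneity = heterogeneity,
                        shape = shapes, rep = seq_len(n_rep),
                        stringsAsFactors = FALSE)
  seeds <- derive_seeds(seed, nrow(combos))
  pv <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cfg <- population_preset(combos$scale[i], combos$heterogeneity[i],
                             combos$shape[i], n_items = n_items,
                             n_obs = n_obs)
    pop <- simulate_population(cfg, seed = seeds[[i]])
    prec <- item_precision(pop)
    pv[i] <- proportion_of_variance(stats::sd(prec$sd), cfg$scale)
  }
  combos$prop_var <- pv
  by_scale <- tapply(combos$prop_var, combos$scale, mean)
  list(by_scale = by_scale[scales], detail = combos)
}
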