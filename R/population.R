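#' Configure a simulated multi-item population
#'
#' Describes a population of items whose scores are drawn from per-item
#' normal distributions, rounded to whole numbers, and clamped to the scale
#' endpoints — the construction used to emulate Likert, percent, and
#' response-latency style instruments. Item means are drawn from
#' Normal(`mu`, `sigma_mu`) and item standard deviations from
#' Normal(`sigma`, `sigma_sigma`); `sigma_sigma` is therefore the
#' heterogeneity knob: how much item variances differ from one another.
#'
#' @param n_items Number of items. Default 30.
#' @param n_obs Scores drawn per item. Default 1000.
#' @param mu Grand mean of the item means, in score units.
#' @param sigma_mu Standard deviation of the item means.
#' @param sigma Grand mean of the item standard deviations.
#' @param sigma_sigma Standard deviation of the item standard deviations
#'   (item-variance heterogeneity).
#' @param scale A [scale_spec()] giving the instrument bounds.
#' @param shape One of `"symmetric"`, `"ceiling"`, `"floor"`. `mu` should be
#'   near the scale midpoint for symmetric items and near the upper bound
#'   for ceiling items; the floor mean mirrors the ceiling mean about the
#'   midpoint (`min + max - mu_ceiling`).
#' @param bimodal_fraction Proportion of items built as equal mixtures of a
#'   ceiling and a floor component. Default 0.
#' @param mu_ceiling,mu_floor Component means used for bimodal items (and for
#'   `shape = "ceiling"`/`"floor"`); defaults come from the preset scales or
#'   the mirror rule.
#' @param seed Optional integer seed; the draw is fully reproducible given
#'   the seed.
#'
#' @return A list of class `population_config`.
#' @seealso [population_preset()] for the nine named benchmark
#'   parameterisations, [simulate_population()] to draw scores.
#' @export
population_config <- function(n_items = 30, n_obs = 1000, mu, sigma_mu, sigma,
                              sigma_sigma, scale,
                              shape = c("symmetric", "ceiling", "floor"),
                              bimodal_fraction = 0,
                              mu_ceiling = NULL, mu_floor = NULL,
                              seed = NULL) {
  shape <- match.arg(shape)
  stopifnot(inherits(scale, "scale_spec"), n_items >= 1, n_obs >= 2,
            sigma > 0, sigma_sigma >= 0, sigma_mu >= 0,
            bimodal_fraction >= 0, bimodal_fraction <= 1)
  if (is.null(mu_ceiling)) {
    mu_ceiling <- switch(shape,
      ceiling = mu,
      floor = scale$minimum + scale$maximum - mu,
      symmetric = if (bimodal_fraction > 0) {
        stop("Supply `mu_ceiling` (the upper component mean) when mixing ",
             "bimodal items into a symmetric configuration.", call. = FALSE)
      } else NA_real_)
  }
  if (is.null(mu_floor)) mu_floor <- scale$minimum + scale$maximum - mu_ceiling
  structure(list(n_items = as.integer(n_items), n_obs = as.integer(n_obs),
                 mu = mu, sigma_mu = sigma_mu, sigma = sigma,
                 sigma_sigma = sigma_sigma, scale = scale, shape = shape,
                 bimodal_fraction = bimodal_fraction,
                 mu_ceiling = mu_ceiling, mu_floor = mu_floor, seed = seed),
            class = "population_config")
}

# Benchmark parameter matrix: three scales x three heterogeneity levels.
# Symmetric means sit at the scale midpoint; ceiling means near the top.
.preset_table <- list(
  likert = list(minimum = 1, maximum = 7, mu = 4, mu_ceiling = 6,
                sigma_mu = 0.25, sigma = 2,
                sigma_sigma = c(small = 0.2, medium = 0.4, large = 0.8)),
  percent = list(minimum = 0, maximum = 100, mu = 50, mu_ceiling = 85,
                 sigma_mu = 10, sigma = 25,
                 sigma_sigma = c(small = 4, medium = 8, large = 16)),
  milliseconds = list(minimum = 0, maximum = 3000, mu = 1000,
                      mu_ceiling = 2500, sigma_mu = 150, sigma = 400,
                      sigma_sigma = c(small = 50, medium = 100, large = 200))
)

#' Named benchmark population presets
#'
#' Returns a ready-made [population_config()] for one of the nine standard
#' simulation conditions: a 7-point Likert scale, a 0-100 percent scale, or a
#' 0-3000 millisecond response-latency scale, each with small, medium, or
#' large heterogeneity of item variances. Symmetric items centre on the
#' scale midpoint; ceiling items centre near the top (6, 85, 2500); floor
#' items mirror the ceiling mean about the midpoint (2, 15, 500).
#'
#' @param scale `"likert"`, `"percent"`, or `"milliseconds"`.
#' @param heterogeneity `"small"`, `"medium"`, or `"large"`.
#' @inheritParams population_config
#' @return A `population_config`.
#' @examples
#' population_preset("likert", "small")
#' @export
population_preset <- function(scale = c("likert", "percent", "milliseconds"),
                              heterogeneity = c("small", "medium", "large"),
                              shape = c("symmetric", "ceiling", "floor"),
                              n_items = 30, n_obs = 1000,
                              bimodal_fraction = 0, seed = NULL) {
  scale <- match.arg(scale)
  heterogeneity <- match.arg(heterogeneity)
  shape <- match.arg(shape)
  p <- .preset_table[[scale]]
  mu <- switch(shape, symmetric = p$mu, ceiling = p$mu_ceiling,
               floor = p$minimum + p$maximum - p$mu_ceiling)
  population_config(n_items = n_items, n_obs = n_obs, mu = mu,
                    sigma_mu = p$sigma_mu, sigma = p$sigma,
                    sigma_sigma = p$sigma_sigma[[heterogeneity]],
                    scale = scale_spec(p$minimum, p$maximum, discrete = TRUE),
                    shape = shape, bimodal_fraction = bimodal_fraction,
                    mu_ceiling = p$mu_ceiling,
                    mu_floor = p$minimum + p$maximum - p$mu_ceiling,
                    seed = seed)
}

# round half away from zero (R's round() is banker's rounding)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# item SDs are Normal(sigma, sigma_sigma) truncated to stay positive by
# redraw; the floor at 0.01*sigma guards against degenerate items
draw_item_sd <- function(n, sigma, sigma_sigma, max_tries = 1000L) {
  lo <- 0.01 * sigma
  # if truncation would discard a large share of the distribution, the
  # redrawn SDs no longer have the requested mean/SD: refuse rather than
  # silently distort
  if (sigma_sigma > 0 && stats::pnorm(lo, sigma, sigma_sigma) > 0.4) {
    stop("`sigma_sigma` is too large relative to `sigma`: truncating item ",
         "SDs to stay positive would reject excessively.", call. = FALSE)
  }
  sds <- stats::rnorm(n, sigma, sigma_sigma)
  tries <- 0L
  while (any(bad <- sds < lo)) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("Could not draw positive item SDs; `sigma_sigma` is too large ",
           "relative to `sigma`.", call. = FALSE)
    }
    sds[bad] <- stats::rnorm(sum(bad), sigma, sigma_sigma)
  }
  sds
}

# finishing step shared by all generators: round to whole numbers, then
# clamp to the scale endpoints
finish_scores <- function(x, scale) {
  if (scale$discrete) x <- round_half_up(x)
  pmin(pmax(x, scale$minimum), scale$maximum)
}

#' Draw scores for one bimodal item
#'
#' A bimodal item mixes two latent subpopulations: half of the scores come
#' from a ceiling component (mean near the top of the scale) and half from a
#' floor component (mean mirrored below the midpoint), each with its own SD
#' drawn from the usual Normal(`sigma`, `sigma_sigma`) machinery. For odd
#' `n_obs` the extra score goes to the ceiling component. Scores are rounded
#' and clamped like any other item.
#'
#' @param config A [population_config()]; `mu_ceiling` and `mu_floor` give
#'   the two component means.
#' @return Numeric vector of `config$n_obs` scores.
#' @export
make_bimodal_item <- function(config) {
  stopifnot(inherits(config, "population_config"))
  n_hi <- ceiling(config$n_obs / 2)
  n_lo <- config$n_obs - n_hi
  sds <- draw_item_sd(2L, config$sigma, config$sigma_sigma)
  x <- c(stats::rnorm(n_hi, config$mu_ceiling, sds[1]),
         stats::rnorm(n_lo, config$mu_floor, sds[2]))
  finish_scores(x, config$scale)
}

#' Simulate a multi-item population
#'
#' Draws `n_obs` scores for each of `n_items` items. Each regular item gets
#' a mean from Normal(`mu`, `sigma_mu`) and an SD from
#' Normal(`sigma`, `sigma_sigma`) (redrawn while non-positive); its scores
#' are normal draws that are then rounded to the nearest whole number and
#' clamped to the scale endpoints, which is how boundary skew (ceiling/floor
#' pile-up) arises. A leading `bimodal_fraction` of the items is instead
#' built by [make_bimodal_item()].
#'
#' @param config A [population_config()] or [population_preset()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A `score_table` with items `"item_1"` ... `"item_k"` and
#'   participants `"p_1"` ... `"p_n"` (participant ids index the draw within
#'   item; there is no cross-item participant linkage).
#' @examples
#' pop <- simulate_population(population_preset("likert", "small", seed = 1))
#' range(pop$score)
#' @export
simulate_population <- function(config, seed = NULL) {
  stopifnot(inherits(config, "population_config"))
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  n_bimodal <- round_half_up(config$bimodal_fraction * config$n_items)
  scores <- vector("list", config$n_items)
  for (i in seq_len(config$n_items)) {
    if (i <= n_bimodal) {
      scores[[i]] <- make_bimodal_item(config)
    } else {
      m <- stats::rnorm(1, config$mu, config$sigma_mu)
      s <- draw_item_sd(1L, config$sigma, config$sigma_sigma)
      scores[[i]] <- finish_scores(stats::rnorm(config$n_obs, m, s),
                                   config$scale)
    }
  }
  out <- data.frame(
    participant = rep(paste0("p_", seq_len(config$n_obs)), config$n_items),
    item = rep(paste0("item_", seq_len(config$n_items)),
               each = config$n_obs),
    score = unlist(scores),
    stringsAsFactors = FALSE
  )
  class(out) <- c("score_table", "data.frame")
  out
}

#' Sample a pilot study from a population
#'
#' Emulates a researcher collecting pilot data: `n_per_item` scores are
#' drawn with replacement from each item's population scores.
#'
#' @param population A `score_table`.
#' @param n_per_item Pilot sample size per item (>= 2).
#' @param seed Optional integer seed.
#' @return A `score_table` with `n_per_item` rows per item.
#' @export
draw_pilot <- function(population, n_per_item, seed = NULL) {
  population <- as_score_table(population)
  if (n_per_item < 2) stop("`n_per_item` must be at least 2.", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  items <- unique(population$item)
  by_item <- split(population$score, factor(population$item, levels = items))
  scores <- lapply(by_item, function(x) {
    x <- x[!is.na(x)]
    x[sample.int(length(x), n_per_item, replace = TRUE)]
  })
  out <- data.frame(
    participant = rep(paste0("p_", seq_len(n_per_item)), length(items)),
    item = rep(items, each = n_per_item),
    score = unlist(scores, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  class(out) <- c("score_table", "data.frame")
  out
}
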