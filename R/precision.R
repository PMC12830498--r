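#' Per-item sample size, mean, SD, and standard error
#'
#' The standard error of an item's mean, SD / sqrt(n) with the n - 1
#' (sample) SD, is the precision quantity the whole planning procedure
#' controls. Missing scores are excluded item-wise; items left with fewer
#' than two scores have no defined SE and are dropped with a warning.
#'
#' @param data A `score_table` (or coercible data frame with columns
#'   `participant`, `item`, `score`).
#' @return A data frame with one row per item: `item`, `n`, `mean`, `sd`,
#'   `se`, ordered by first appearance.
#' @examples
#' pilot <- simulate_population(population_preset("likert", "small", seed = 2))
#' head(item_precision(pilot))
#' @export
item_precision <- function(data) {
  data <- as_score_table(data)
  items <- unique(data$item)
  f <- factor(data$item, levels = items)
  ok <- !is.na(data$score)
  n <- as.vector(tapply(ok, f, sum))
  m <- as.vector(tapply(data$score[ok], f[ok], mean))
  s <- as.vector(tapply(data$score[ok], f[ok], stats::sd))
  data.frame(item = items, n = n, mean = m, sd = s, se = s / sqrt(n),
             stringsAsFactors = FALSE)
}

#' Empirical decile cutoff of a set of standard errors
#'
#' The SE cutoff is the empirical quantile of the per-item SEs at the chosen
#' decile, computed by linear interpolation between order statistics at
#' position h = (n - 1) * decile + 1 (the type-7 quantile). The 4th decile
#' is the recommended default: strict enough that most items end up better
#' measured than the typical pilot item, without the runaway sample sizes
#' the lowest deciles produce.
#'
#' @param ses Numeric vector of per-item standard errors (>= 2 values).
#' @param decile Quantile level in (0, 1). Default 0.4.
#' @return The SE value at the decile.
#' @examples
#' decile_cutoff(1:10, 0.4)  # 4.6
#' @export
decile_cutoff <- function(ses, decile = 0.4) {
  stopifnot(is.numeric(ses))
  ses <- ses[!is.na(ses)]
  if (length(ses) < 2) stop("Need at least 2 SE values.", call. = FALSE)
  if (!(decile > 0 && decile < 1)) {
    stop("`decile` must lie strictly between 0 and 1.", call. = FALSE)
  }
  unname(stats::quantile(ses, probs = decile, type = 7, names = FALSE))
}

#' Proportion of possible variance
#'
#' A scale-free heterogeneity summary: the SD of the per-item standard
#' deviations divided by half the scale range, sqrt((max - min)^2 / 4).
#' It expresses how much item variances differ relative to the most
#' variance the instrument could support, and is the heterogeneity input of
#' the regression correction.
#'
#' @param sd_item_sd SD of the per-item sample SDs (score units).
#' @param scale A [scale_spec()].
#' @return Dimensionless proportion (>= 0).
#' @examples
#' proportion_of_variance(0.28, scale_spec(1, 5))     # 0.14
#' proportion_of_variance(140.83, scale_spec(0, 3480))  # ~0.081
#' @export
proportion_of_variance <- function(sd_item_sd, scale) {
  stopifnot(inherits(scale, "scale_spec"), sd_item_sd >= 0)
  sd_item_sd / sqrt((scale$maximum - scale$minimum)^2 / 4)
}

#' Compute the precision cutoff bundle for a pilot dataset
#'
#' Bundles everything the planning steps downstream need from the pilot:
#' per-item precision, the decile SE cutoff (which doubles as the
#' sequential stopping rule), the SD of the item SDs, the proportion of
#' possible variance, and a representative pilot n (the ceiling of the mean
#' per-item n, so 28.52 observed scores per item reports as 29).
#'
#' @inheritParams item_precision
#' @param scale A [scale_spec()]; `NULL` infers bounds from the data with a
#'   warning.
#' @param decile Cutoff decile in (0, 1). Default 0.4.
#' @return An object of class `cutoff_result`: a list with `per_item` (the
#'   [item_precision()] table), `decile`, `se_cutoff`, `sd_item_sd`,
#'   `prop_var`, `pilot_n`, and `scale`.
#' @examples
#' pop <- simulate_population(population_preset("likert", "small", seed = 3))
#' pilot <- draw_pilot(pop, 30, seed = 4)
#' calculate_cutoff(pilot, scale_spec(1, 7))
#' @export
calculate_cutoff <- function(data, scale = NULL, decile = 0.4) {
  data <- as_score_table(data)
  if (is.null(scale)) {
    scale <- infer_scale(data)
    warning("No scale bounds declared; inferred [", scale$minimum, ", ",
            scale$maximum, "] from the data.", call. = FALSE)
  }
  per_item <- item_precision(data)
  sd_item_sd <- stats::sd(per_item$sd)
  structure(list(
    per_item = per_item,
    decile = decile,
    se_cutoff = decile_cutoff(per_item$se, decile),
    sd_item_sd = sd_item_sd,
    prop_var = proportion_of_variance(sd_item_sd, scale),
    pilot_n = as.integer(ceiling(mean(per_item$n))),
    scale = scale
  ), class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("<cutoff_result> %d items, pilot n = %d\n",
              nrow(x$per_item), x$pilot_n))
  cat(sprintf("  SE cutoff (decile %.2f): %.4g\n", x$decile, x$se_cutoff))
  cat(sprintf("  SD of item SDs: %.4g; proportion of possible variance: %.4g\n",
              x$sd_item_sd, x$prop_var))
  invisible(x)
}

#' Check the sequential stopping rule against current data
#'
#' In an adaptive design the cutoff SE acts as the stopping rule: an item is
#' "stopped" (measured precisely enough) once its current SE falls strictly
#' below the cutoff, and data collection can end when every item has
#' stopped.
#'
#' @param current A `score_table` of the data collected so far.
#' @param cutoff Positive SE cutoff (e.g., `cutoff_result$se_cutoff`).
#' @return A list with `per_item` (the precision table plus a logical
#'   `stopped` column) and `all_stopped`.
#' @export
check_stop <- function(current, cutoff) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, cutoff > 0)
  per_item <- item_precision(current)
  per_item$stopped <- per_item$se < cutoff
  list(per_item = per_item, all_stopped = all(per_item$stopped))
}
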