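#' Published correction-regression coefficient sets
#'
#' The regression correction approximates the decay-corrected sample size
#' from quantities a researcher observes after the bootstrap step: projected
#' sample size, pilot sample size, proportion of possible variance, and the
#' percent of items below the cutoff ("power", in percent units). Two
#' published nine-term coefficient sets are available: the default was fit
#' for the recommended 4th-decile cutoff; the alternate pools all decile
#' cutoffs and suits non-default deciles.
#'
#' @param set `"fourth_decile"` (default) or `"all_deciles"`.
#' @return A named numeric vector of class `correction_coefficients` with
#'   elements `intercept`, `b_projected`, `b_pilot`, `b_log2_projected`,
#'   `b_log2_pilot`, `b_log2_power`, `b_prop_var`, `b_log2_prop_var`,
#'   `b_power`.
#' @export
correction_coefficients <- function(set = c("fourth_decile", "all_deciles")) {
  set <- match.arg(set)
  co <- switch(set,
    fourth_decile = c(intercept = 206.589, b_projected = 0.368,
                      b_pilot = -0.770, b_log2_projected = 27.541,
                      b_log2_pilot = 2.583, b_log2_power = -66.151,
                      b_prop_var = 16.405, b_log2_prop_var = -1.367,
                      b_power = 1.088),
    all_deciles = c(intercept = 111.049, b_projected = 0.429,
                    b_pilot = 15.434, b_log2_projected = -0.718,
                    b_log2_pilot = 0.606, b_log2_power = 19.522,
                    b_prop_var = -0.729, b_log2_prop_var = 4.655,
                    b_power = -39.367)
  )
  structure(co, class = c("correction_coefficients", "numeric"), set = set)
}

#' Exponential-decay correction factor for pilot-size sensitivity
#'
#' Raw bootstrap projections grow roughly linearly with the pilot sample
#' size: a bigger pilot always suggests a slightly bigger study, which
#' contradicts the asymptotic ("levelling off") behaviour of power curves.
#' The decay factor
#' \deqn{1 - \left(\sqrt{\frac{N_{pilot} - n_{min}}{N_{pilot}}}\right)^{\log_2 N_{pilot}}}
#' multiplies the projected size, equals 1 when the pilot is no larger than
#' the smallest simulated size (no decay), and shrinks as the pilot grows
#' so that recommendations flatten out.
#'
#' @param n_pilot Pilot sample size (>= `min_sim`).
#' @param min_sim Smallest simulated sample size on the grid (>= 1),
#'   typically the grid start (default 20).
#' @return Factor in `[0, 1]`.
#' @examples
#' decay_factor(20, 20)   # 1: no decay at the grid start
#' decay_factor(100, 20)  # ~0.523
#' @export
decay_factor <- function(n_pilot, min_sim = 20) {
  stopifnot(is.numeric(n_pilot), is.numeric(min_sim), min_sim >= 1)
  if (any(n_pilot < min_sim)) {
    stop("`n_pilot` must be at least `min_sim`.", call. = FALSE)
  }
  1 - sqrt((n_pilot - min_sim) / n_pilot)^log2(n_pilot)
}

#' Apply the decay correction to a projected sample size
#'
#' @param projected_n Projected sample size from the bootstrap step.
#' @inheritParams decay_factor
#' @return `projected_n * decay_factor(n_pilot, min_sim)` (real).
#' @export
apply_decay <- function(projected_n, n_pilot, min_sim = 20) {
  projected_n * decay_factor(n_pilot, min_sim)
}

#' Regression-corrected sample size
#'
#' Evaluates the nine-term linear model: each of projected sample size,
#' pilot sample size, power, and proportion of variance enters both raw and
#' log2-transformed. Power is in percent units (80, not 0.80).
#'
#' @param projected_n Projected sample size (>= 1).
#' @param pilot_n Pilot sample size (>= 1).
#' @param prop_var Proportion of possible variance (> 0; the log2 term is
#'   undefined at 0).
#' @param power_percent Percent of items below the cutoff, in (0, 100].
#' @param coeffs A [correction_coefficients()] set.
#' @return Corrected sample size (real; may need rounding up and flooring
#'   at the grid start by the caller).
#' @examples
#' regression_correction(45, 29, 0.14, 80)  # ~39.6
#' @export
regression_correction <- function(projected_n, pilot_n, prop_var,
                                  power_percent,
                                  coeffs = correction_coefficients()) {
  stopifnot(projected_n >= 1, pilot_n >= 1,
            power_percent > 0, power_percent <= 100)
  if (any(prop_var <= 0)) {
    stop("`prop_var` must be positive (its log2 enters the model); ",
         "floor tiny values at a small positive constant if needed.",
         call. = FALSE)
  }
  co <- coeffs
  unname(co["intercept"] +
         co["b_projected"] * projected_n +
         co["b_pilot"] * pilot_n +
         co["b_log2_projected"] * log2(projected_n) +
         co["b_log2_pilot"] * log2(pilot_n) +
         co["b_log2_power"] * log2(power_percent) +
         co["b_prop_var"] * prop_var +
         co["b_log2_prop_var"] * log2(prop_var) +
         co["b_power"] * power_percent)
}

#' Inflate a sample size for expected data loss
#'
#' Divides the corrected sample size by the proportion of trials expected
#' to be retained (e.g., 0.93 when 7% of responses are typically unusable)
#' and rounds up to a whole participant.
#'
#' @param n Corrected sample size (real).
#' @param retention Proportion of data retained, in (0, 1].
#' @return Integer final sample size, `ceiling(n / retention)`.
#' @examples
#' loss_adjust(50, 0.8)  # 63
#' @export
loss_adjust <- function(n, retention = 1) {
  stopifnot(is.numeric(retention), length(retention) == 1)
  if (retention <= 0 || retention > 1) {
    stop("`retention` must lie in (0, 1].", call. = FALSE)
  }
  as.integer(ceiling(n / retention))
}

#' Assemble the final sample-size plan across power levels
#'
#' For each target power level the percent-below-cutoff curve is scanned for
#' its first crossing (the projected sample size), the regression correction
#' is applied, and the result is inflated for expected data loss. By
#' default the power entering the regression is the percent actually
#' achieved at the crossing (e.g., 82.5 when 80 was requested); setting
#' `nominal_power = TRUE` uses the requested levels instead. Corrected
#' values below the smallest simulated size are floored there with a
#' warning. The smallest reached level is designated the minimum sample
#' size and the largest the maximum; the cutoff SE is carried along as the
#' sequential stopping rule.
#'
#' @param summary A `proportion_summary` from [calculate_proportion()].
#' @param pilot_n Pilot sample size (see `cutoff_result$pilot_n`).
#' @param prop_var Proportion of possible variance (> 0).
#' @param power_levels Target percent levels. Default `c(80, 85, 90, 95)`.
#' @param retention Proportion of data retained, in (0, 1]. Default 1.
#' @param coeffs A [correction_coefficients()] set.
#' @param se_cutoff Optional cutoff SE to report as the stopping rule.
#' @param nominal_power Use the nominal levels in the regression instead of
#'   the achieved percents. Default `FALSE`.
#' @param floor_n Floor for corrected sizes; defaults to the smallest grid
#'   size in `summary`.
#' @return An object of class `plan_result`: a list with `levels` (a data
#'   frame with one row per power level: `power_level`, `projected_n`,
#'   `power_used`, `corrected_n`, `final_n`, `reached`), `se_cutoff`,
#'   `minimum_n`, `maximum_n`, and `retention`.
#' @export
calculate_correction <- function(summary, pilot_n, prop_var,
                                 power_levels = c(80, 85, 90, 95),
                                 retention = 1,
                                 coeffs = correction_coefficients(),
                                 se_cutoff = NA_real_,
                                 nominal_power = FALSE,
                                 floor_n = NULL) {
  stopifnot(is.data.frame(summary), pilot_n >= 1, prop_var > 0,
            all(power_levels > 0 & power_levels <= 100))
  if (is.null(floor_n)) floor_n <- min(summary$sample_size)
  rows <- lapply(power_levels, function(lv) {
    proj <- projected_n(summary, lv / 100)
    if (!proj$reached) {
      return(data.frame(power_level = lv, projected_n = NA_integer_,
                        power_used = NA_real_, corrected_n = NA_real_,
                        final_n = NA_integer_, reached = FALSE))
    }
    pw <- if (nominal_power) lv else 100 * proj$achieved
    corr <- regression_correction(proj$sample_size, pilot_n, prop_var, pw,
                                  coeffs = coeffs)
    if (corr < floor_n) {
      warning("Corrected sample size ", round(corr, 2), " for the ", lv,
              "% level fell below the smallest simulated size; floored at ",
              floor_n, ".", call. = FALSE)
      corr <- floor_n
    }
    data.frame(power_level = lv, projected_n = proj$sample_size,
               power_used = pw, corrected_n = corr,
               final_n = loss_adjust(corr, retention), reached = TRUE)
  })
  levels_df <- do.call(rbind, rows)
  reached <- levels_df[levels_df$reached, , drop = FALSE]
  structure(list(
    levels = levels_df,
    se_cutoff = se_cutoff,
    minimum_n = if (nrow(reached)) reached$final_n[which.min(reached$power_level)] else NA_integer_,
    maximum_n = if (nrow(reached)) reached$final_n[which.max(reached$power_level)] else NA_integer_,
    retention = retention
  ), class = "plan_result")
}

#' @export
print.plan_result <- function(x, ...) {
  cat("<plan_result>\n")
  print(x$levels, row.names = FALSE)
  if (!is.na(x$se_cutoff)) {
    cat(sprintf("  Stopping rule (SE cutoff): %.4g\n", x$se_cutoff))
  }
  cat(sprintf("  Minimum N: %s   Maximum N: %s   (retention %.2f)\n",
              x$minimum_n, x$maximum_n, x$retention))
  if (any(!x$levels$reached)) {
    cat("  Note: level(s) ",
        paste(x$levels$power_level[!x$levels$reached], collapse = ", "),
        "% never reached on the simulated grid.\n", sep = "")
  }
  invisible(x)
}

#' Run the full six-step planning pipeline on pilot data
#'
#' Convenience wrapper chaining [calculate_cutoff()], [simulate_samples()],
#' [calculate_proportion()], and [calculate_correction()].
#'
#' @inheritParams calculate_cutoff
#' @param grid A [sample_grid()].
#' @inheritParams calculate_correction
#' @param seed Optional seed for the bootstrap.
#' @return A `plan_result` with the `cutoff_result` attached as
#'   `$cutoff` and the `proportion_summary` as `$summary`.
#' @examples
#' pop <- simulate_population(population_preset("likert", "small",
#'                                              n_obs = 500, seed = 7))
#' pilot <- draw_pilot(pop, 30, seed = 8)
#' plan_study(pilot, scale_spec(1, 7),
#'            grid = sample_grid(20, 100, 10, nsim = 50), seed = 9)
#' @export
plan_study <- function(data, scale = NULL, decile = 0.4,
                       grid = sample_grid(), power_levels = c(80, 85, 90, 95),
                       retention = 1, coeffs = correction_coefficients(),
                       nominal_power = FALSE, seed = NULL) {
  data <- as_score_table(data)
  cutoff <- calculate_cutoff(data, scale = scale, decile = decile)
  ses <- simulate_samples(data, grid, seed = seed)
  summary <- calculate_proportion(ses, cutoff$se_cutoff)
  plan <- calculate_correction(summary, pilot_n = cutoff$pilot_n,
                               prop_var = cutoff$prop_var,
                               power_levels = power_levels,
                               retention = retention, coeffs = coeffs,
                               se_cutoff = cutoff$se_cutoff,
                               nominal_power = nominal_power)
  plan$cutoff <- cutoff
  plan$summary <- summary
  plan
}
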