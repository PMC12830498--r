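#' Define the grid of candidate sample sizes for bootstrap projection
#'
#' Candidate per-item sample sizes run from `start` to `stop` in steps of
#' `step`, with `nsim` bootstrap replicates at each size. Starting below 20
#' participants is rarely informative, and 500-1000 replicates give stable
#' percent-below-cutoff curves.
#'
#' @param start Smallest candidate size (>= 2). Default 20.
#' @param stop Largest candidate size (>= `start`).
#' @param step Grid increment (>= 1). Default 5.
#' @param nsim Bootstrap replicates per size (>= 1). Default 500.
#' @param seed Optional integer seed.
#' @return A list of class `sample_grid` with a `sizes` vector.
#' @export
sample_grid <- function(start = 20, stop = 300, step = 5, nsim = 500,
                        seed = NULL) {
  stopifnot(start >= 2, stop >= start, step >= 1, nsim >= 1)
  structure(list(start = as.integer(start), stop = as.integer(stop),
                 step = as.integer(step), nsim = as.integer(nsim),
                 sizes = seq(as.integer(start), as.integer(stop),
                             by = as.integer(step)),
                 seed = seed),
            class = "sample_grid")
}

#' Bootstrap item standard errors across a sample-size grid
#'
#' For every candidate sample size n on the grid, every replicate, and every
#' item, n scores are drawn with replacement from that item's pilot scores
#' and the SE of the resample is recorded. Resampling is per-item (items may
#' have unequal pilot n); missing pilot scores are excluded before drawing.
#'
#' @param pilot A `score_table` of pilot (or simulated population) data.
#' @param grid A [sample_grid()].
#' @param seed Optional seed overriding `grid$seed`.
#' @return A 3-d numeric array of simulated SEs with dimensions
#'   size x replicate x item, dimnames carrying the sizes and item labels,
#'   and class `simulated_se`.
#' @examples
#' pop <- simulate_population(population_preset("likert", "small",
#'                                              n_obs = 200, seed = 5))
#' ses <- simulate_samples(pop, sample_grid(20, 40, 10, nsim = 20, seed = 6))
#' dim(ses)
#' @export
simulate_samples <- function(pilot, grid, seed = NULL) {
  pilot <- as_score_table(pilot)
  stopifnot(inherits(grid, "sample_grid"))
  if (is.null(seed)) seed <- grid$seed
  if (!is.null(seed)) set.seed(seed)
  items <- unique(pilot$item)
  by_item <- lapply(split(pilot$score, factor(pilot$item, levels = items)),
                    function(x) x[!is.na(x)])
  out <- array(NA_real_,
               dim = c(length(grid$sizes), grid$nsim, length(items)),
               dimnames = list(sample_size = grid$sizes, replicate = NULL,
                               item = items))
  for (j in seq_along(items)) {
    x <- by_item[[j]]
    for (i in seq_along(grid$sizes)) {
      n <- grid$sizes[i]
      draws <- matrix(x[sample.int(length(x), n * grid$nsim, replace = TRUE)],
                      nrow = n, ncol = grid$nsim)
      mu <- colMeans(draws)
      ss <- colSums(draws^2) - n * mu^2
      ss[ss < 0] <- 0  # guard against negative round-off
      out[i, , j] <- sqrt(ss / (n - 1)) / sqrt(n)
    }
  }
  class(out) <- c("simulated_se", class(out))
  out
}

#' Percent of items below the cutoff per candidate sample size
#'
#' For each grid size, the fraction of items whose simulated SE falls
#' strictly below the cutoff is computed within each replicate and then
#' averaged over replicates, yielding the percent-below-cutoff curve that
#' drives sample-size selection.
#'
#' @param ses A `simulated_se` array from [simulate_samples()].
#' @param cutoff Positive SE cutoff (typically `cutoff_result$se_cutoff`).
#' @return A data frame of class `proportion_summary` with columns
#'   `sample_size` and `percent_below` (in `[0, 1]`).
#' @export
calculate_proportion <- function(ses, cutoff) {
  stopifnot(inherits(ses, "simulated_se") || (is.array(ses) &&
                                              length(dim(ses)) == 3),
            is.numeric(cutoff), length(cutoff) == 1, cutoff > 0)
  below <- ses < cutoff
  # mean over items (dim 3) gives per-replicate fractions; then over reps
  per_rep <- apply(below, c(1, 2), mean)
  out <- data.frame(
    sample_size = as.integer(dimnames(ses)[[1]]),
    percent_below = rowMeans(per_rep)
  )
  class(out) <- c("proportion_summary", "data.frame")
  out
}

#' Smallest sample size reaching a target percent of precise items
#'
#' Scans the percent-below-cutoff curve in increasing sample size and
#' returns the first size whose averaged percent meets or exceeds the
#' target level, together with the percent actually achieved there (which
#' may overshoot the nominal level, e.g. 82.5% when asking for 80%). If no
#' size on the grid qualifies the result is a not-reached marker (`NA`
#' sample size).
#'
#' @param summary A `proportion_summary` from [calculate_proportion()].
#' @param level Target fraction in (0, 1].
#' @return A list with `sample_size` (integer or `NA`), `achieved` (fraction
#'   or `NA`), and `reached` (logical).
#' @export
projected_n <- function(summary, level) {
  stopifnot(is.data.frame(summary), nrow(summary) >= 1,
            all(c("sample_size", "percent_below") %in% names(summary)),
            level > 0, level <= 1)
  ord <- order(summary$sample_size)
  hit <- which(summary$percent_below[ord] >= level)
  if (!length(hit)) {
    return(list(sample_size = NA_integer_, achieved = NA_real_,
                reached = FALSE))
  }
  i <- ord[hit[1]]
  list(sample_size = as.integer(summary$sample_size[i]),
       achieved = summary$percent_below[i], reached = TRUE)
}
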