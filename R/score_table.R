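#' Declare the bounds of a measurement scale
#'
#' A scale specification records the theoretical minimum and maximum of the
#' instrument (e.g., 1 and 7 for a 7-point Likert scale) and whether scores
#' are discrete (rounded to whole numbers). Half the range of the scale is
#' the denominator of the proportion-of-possible-variance heterogeneity
#' summary, so the bounds should describe the instrument, not the observed
#' data, whenever the instrument is bounded.
#'
#' @param minimum Lower bound of the scale.
#' @param maximum Upper bound of the scale; must exceed `minimum`.
#' @param discrete Logical; `TRUE` when scores are whole numbers.
#'
#' @return An object of class `scale_spec`: a list with elements `minimum`,
#'   `maximum`, and `discrete`.
#' @examples
#' scale_spec(1, 7)
#' scale_spec(0, 100, discrete = TRUE)
#' @export
scale_spec <- function(minimum, maximum, discrete = TRUE) {
  stopifnot(is.numeric(minimum), is.numeric(maximum), length(minimum) == 1,
            length(maximum) == 1, is.finite(minimum), is.finite(maximum))
  if (maximum <= minimum) {
    stop("`maximum` must be strictly greater than `minimum`.", call. = FALSE)
  }
  structure(list(minimum = as.numeric(minimum),
                 maximum = as.numeric(maximum),
                 discrete = isTRUE(discrete)),
            class = "scale_spec")
}

#' @export
print.scale_spec <- function(x, ...) {
  cat(sprintf("<scale_spec> [%g, %g], %s scores\n", x$minimum, x$maximum,
              if (x$discrete) "discrete" else "continuous"))
  invisible(x)
}

#' Infer scale bounds from observed scores
#'
#' Convenience for unbounded or undeclared instruments: bounds are taken as
#' the observed score range, mirroring the convention of falling back on the
#' data when the scale itself has no fixed endpoints.
#'
#' @param data A score table (see [as_score_table()]).
#' @param discrete Logical; passed through to [scale_spec()].
#' @return A `scale_spec`.
#' @export
infer_scale <- function(data, discrete = NULL) {
  data <- as_score_table(data)
  sc <- data$score[!is.na(data$score)]
  if (is.null(discrete)) discrete <- all(sc == round(sc))
  scale_spec(min(sc), max(sc), discrete = discrete)
}

#' Validate and canonicalise long-format item score data
#'
#' The universal data container of the package is a long-format data frame
#' with one row per participant-by-item observation and columns
#' `participant`, `item`, and `score`. Identifiers are treated as opaque
#' strings. Missing scores are allowed and are excluded item-wise from all
#' precision computations; items left with fewer than two non-missing scores
#' have no defined standard error and are dropped with a warning.
#'
#' @param data A data frame containing the three columns (any order).
#' @param participant,item,score Column names in `data` holding the
#'   participant identifier, item identifier, and numeric score.
#' @param scale Optional [scale_spec()]; when supplied, all non-missing
#'   scores must lie within its bounds.
#'
#' @return A data frame of class `score_table` with columns `participant`,
#'   `item` (character) and `score` (numeric).
#' @examples
#' df <- data.frame(id = rep(1:3, each = 2),
#'                  word = rep(c("cat", "dog"), 3),
#'                  rating = c(5, 4, 6, 3, 5, NA))
#' as_score_table(df, participant = "id", item = "word", score = "rating")
#' @export
as_score_table <- function(data, participant = "participant", item = "item",
                           score = "score", scale = NULL) {
  if (inherits(data, "score_table") &&
      identical(c(participant, item, score),
                c("participant", "item", "score"))) {
    return(data)
  }
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(c(participant, item, score), names(data))
  if (length(missing_cols)) {
    stop("Column(s) not found in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(participant = as.character(data[[participant]]),
                    item = as.character(data[[item]]),
                    score = as.numeric(data[[score]]),
                    stringsAsFactors = FALSE)
  if (anyNA(out$item)) {
    stop("Every row must carry a non-missing item identifier.", call. = FALSE)
  }
  if (!is.null(scale)) {
    stopifnot(inherits(scale, "scale_spec"))
    sc <- out$score[!is.na(out$score)]
    if (length(sc) && (min(sc) < scale$minimum || max(sc) > scale$maximum)) {
      stop("Scores fall outside the declared scale bounds [",
           scale$minimum, ", ", scale$maximum, "].", call. = FALSE)
    }
  }
  n_ok <- tapply(!is.na(out$score), out$item, sum)
  thin <- names(n_ok)[n_ok < 2]
  if (length(thin)) {
    warning("Dropping ", length(thin),
            " item(s) with fewer than 2 non-missing scores: ",
            paste(utils::head(thin, 5), collapse = ", "),
            if (length(thin) > 5) ", ..." else "", call. = FALSE)
    out <- out[!(out$item %in% thin), , drop = FALSE]
    rownames(out) <- NULL
  }
  if (!nrow(out)) stop("No items with at least 2 scores remain.", call. = FALSE)
  class(out) <- c("score_table", "data.frame")
  out
}

#' Read an item score table from a delimited text file
#'
#' Reads CSV (default) or TSV files into the long-format container used
#' throughout the package. The delimiter is taken from the file extension
#' (`.tsv`/`.txt` tab, otherwise comma) unless given explicitly.
#'
#' @inheritParams as_score_table
#' @param path Path to a delimited text file.
#' @param sep Field separator; `NULL` (default) infers it from the extension.
#' @return A `score_table` data frame.
#' @seealso [as_score_table()], [wide_to_long()]
#' @export
read_score_table <- function(path, participant = "participant", item = "item",
                             score = "score", sep = NULL, scale = NULL) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  as_score_table(raw, participant = participant, item = item, score = score,
                 scale = scale)
}

#' Reshape wide item data (one column per item) to long format
#'
#' Many multi-item datasets arrive with one row per participant and one
#' column per item. This helper melts such a table into the long
#' participant/item/score layout; empty cells become missing scores.
#'
#' @param data A data frame whose first (or named) column identifies the
#'   participant and whose remaining columns are items.
#' @param participant Name of the participant column. Default: first column.
#' @return A `score_table` data frame with one row per (participant, item).
#' @examples
#' wide <- data.frame(id = 1:2, a = c(3, 4), b = c(5, NA))
#' wide_to_long(wide)
#' @export
wide_to_long <- function(data, participant = names(data)[1]) {
  stopifnot(is.data.frame(data), participant %in% names(data))
  item_cols <- names(data)[names(data) != participant]
  if (!length(item_cols)) stop("No item columns found.", call. = FALSE)
  if (anyDuplicated(item_cols)) {
    stop("Duplicate item column names: ",
         paste(unique(item_cols[duplicated(item_cols)]), collapse = ", "),
         call. = FALSE)
  }
  # one row per cell, empty cells kept as missing scores; the n >= 2
  # retention rule applies downstream, not at reshape time
  long <- data.frame(
    participant = rep(as.character(data[[participant]]), times = length(item_cols)),
    item = rep(item_cols, each = nrow(data)),
    score = as.numeric(unlist(data[item_cols], use.names = FALSE)),
    stringsAsFactors = FALSE
  )
  class(long) <- c("score_table", "data.frame")
  long
}

#' Reshape a long score table back to wide format
#'
#' Inverse of [wide_to_long()] for tables with one observation per
#' (participant, item) pair.
#'
#' @param data A `score_table` (or coercible data frame).
#' @return A data frame with a `participant` column and one column per item.
#' @export
long_to_wide <- function(data) {
  data <- as_score_table(data)
  if (anyDuplicated(data[c("participant", "item")])) {
    stop("long_to_wide() needs at most one score per (participant, item).",
         call. = FALSE)
  }
  items <- unique(data$item)
  parts <- unique(data$participant)
  mat <- matrix(NA_real_, nrow = length(parts), ncol = length(items),
                dimnames = list(parts, items))
  mat[cbind(match(data$participant, parts), match(data$item, items))] <-
    data$score
  out <- data.frame(participant = parts, mat, check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Reconstruct approximate pilot data from per-item summaries
#'
#' When only item means and standard deviations are available (e.g., from a
#' published table), pilot-like data can be regenerated by drawing `n` normal
#' scores per item with the reported moments. This is a convenience
#' approximation only: the normal shape, and any rounding or clamping of the
#' original instrument, are assumptions the reconstruction cannot recover.
#'
#' @param summaries Data frame with columns `item`, `mean`, `sd`, and
#'   optionally `n` (per-item sample size).
#' @param n Default per-item n when `summaries` has no `n` column.
#' @param seed Optional integer seed for reproducibility.
#' @return A `score_table`.
#' @export
reconstruct_pilot <- function(summaries, n = NULL, seed = NULL) {
  stopifnot(is.data.frame(summaries),
            all(c("item", "mean", "sd") %in% names(summaries)))
  ns <- if ("n" %in% names(summaries)) summaries$n else rep(n, nrow(summaries))
  if (is.null(ns) || anyNA(ns) || any(ns < 2)) {
    stop("Per-item n must be supplied (>= 2) via `summaries$n` or `n`.",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  scores <- mapply(function(m, s, k) stats::rnorm(k, m, s),
                   summaries$mean, summaries$sd, ns, SIMPLIFY = FALSE)
  as_score_table(data.frame(
    participant = unlist(lapply(ns, seq_len)),
    item = rep(as.character(summaries$item), times = ns),
    score = unlist(scores),
    stringsAsFactors = FALSE
  ))
}
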