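# Shared fixtures and independent oracles for the test suite.

# a small balanced long table: 4 items x 6 participants, integers on [1, 7]
toy_pilot <- function(seed = 101) {
  set.seed(seed)
  data.frame(
    participant = rep(paste0("p", 1:6), 4),
    item = rep(paste0("it", 1:4), each = 6),
    score = sample(1:7, 24, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# independent interpolating-quantile oracle: linear interpolation between
# order statistics at position h = (n - 1) * q + 1, written from scratch
quantile_oracle <- function(x, q) {
  x <- sort(x)
  h <- (length(x) - 1) * q + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
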