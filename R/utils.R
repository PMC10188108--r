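#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows n row_number across
#' @importFrom stats sd var qnorm pnorm dnorm rnorm runif rbinom rexp
#'   lm coef vcov fisher.test wilcox.test kruskal.test p.adjust approx
#'   cor rnbinom prcomp hclust cutree as.dist dist fft ks.test complete.cases
#'   quantile median setNames
#' @importFrom utils head tail
NULL

#' Circular hour arithmetic
#'
#' Helpers for working on the zeitgeber clock: `wrap_hours()` maps onto
#' \[0, period), `wrap_signed()` maps a difference onto (-period/2,
#' period/2\], and `circ_dist_hours()` is the circular distance in
#' \[0, period/2\].
#'
#' @param x,a,b Hours.
#' @param period Clock period in hours (default 24).
#' @return Numeric vector of hours.
#' @name hour-arithmetic
NULL

#' @rdname hour-arithmetic
#' @export
wrap_hours <- function(x, period = 24) {
  x %% period
}

#' @rdname hour-arithmetic
#' @export
wrap_signed <- function(x, period = 24) {
  w <- (x + period / 2) %% period - period / 2
  ifelse(w == -period / 2, period / 2, w)
}

#' @rdname hour-arithmetic
#' @export
circ_dist_hours <- function(a, b, period = 24) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

hours_to_rad <- function(h, period = 24) 2 * pi * h / period
rad_to_hours <- function(r, period = 24) wrap_hours(r * period / (2 * pi), period)

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1].", name),
          class = "zeitconflict_invalid_config")
  }
  invisible(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name),
          class = "zeitconflict_invalid_config")
  }
  invisible(x)
}

# Centered moving average over an even window of `width` bins: bin t averages
# bins t - width/2 ... t + width/2 - 1. Partial windows at the edges use the
# available bins so the output keeps its length.
moving_average_centered <- function(x, width) {
  n <- length(x)
  half <- width %/% 2
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half - 1L + width %% 2)
    mean(x[lo:hi])
  }, numeric(1))
}
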