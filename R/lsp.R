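# Classical variance-normalised Lomb-Scargle power for a matrix of series
# sharing one time grid. Returns length(periods) x ncol(Y).
lsp_power_matrix <- function(t, Y, periods) {
  Y <- as.matrix(Y)
  n <- length(t)
  Yc <- sweep(Y, 2, colMeans(Y))
  ss <- colSums(Yc^2) / (n - 1)
  P <- matrix(0, length(periods), ncol(Y))
  for (k in seq_along(periods)) {
    w <- 2 * pi / periods[k]
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    cc <- sum(ct^2); sc <- sum(st^2)
    P[k, ] <- (drop(crossprod(ct, Yc))^2 / cc +
               drop(crossprod(st, Yc))^2 / sc) / 2
  }
  ok <- ss > 0
  P[, ok] <- sweep(P[, ok, drop = FALSE], 2, ss[ok], `/`)
  P[, !ok] <- 0
  P
}

# Normalise a user-facing series to a sorted (time_h, value) tibble.
as_series <- function(series) {
  stopifnot(is.data.frame(series), all(c("time_h", "value") %in% names(series)))
  series |> arrange(.data$time_h) |> select("time_h", "value")
}

rhythm_result <- function(method, p_value = NA_real_, p_adj = NA_real_,
                          statistic = NA_real_, period_h = NA_real_,
                          phase_h = NA_real_, amplitude = NA_real_,
                          n_perm = NA_integer_) {
  tibble(method = method, p_value = p_value, p_adj = p_adj,
         statistic = statistic, period_h = period_h, phase_h = phase_h,
         amplitude = amplitude, n_perm = n_perm)
}

# Cosinor phase (time of fitted maximum) and amplitude at a fixed period.
cosinor_phase_amp <- function(t, y, period) {
  w <- 2 * pi / period
  X <- cbind(1, cos(w * t), sin(w * t))
  b <- tryCatch(qr.coef(qr(X), y), error = function(e) c(NA, 0, 0))
  A <- sqrt(b[2]^2 + b[3]^2)
  phi <- if (A > 0) wrap_hours(atan2(b[3], b[2]) / w, period) else 0
  list(phase_h = phi, amplitude = A)
}

#' Lomb-Scargle periodogram of an (evenly or unevenly sampled) series
#'
#' Computes the classical variance-normalised Lomb-Scargle power over a grid
#' of candidate periods. A constant series gets zero power everywhere.
#'
#' @param series Data frame with columns `time_h` and `value`.
#' @param period_lo,period_hi Period search bounds in hours (defaults 20-28;
#'   use 10-14 for circatidal screens).
#' @param period_step Grid resolution, hours.
#' @return An object of class `lsp_spectrum`: a tibble (`period_h`, `power`)
#'   with attributes `peak_period_h` and `peak_power`.
#' @examples
#' s <- tibble::tibble(time_h = 0:71, value = cos(2 * pi * (0:71 - 18) / 24))
#' sp <- lsp_power(s)
#' attr(sp, "peak_period_h")
#' @export
lsp_power <- function(series, period_lo = 20, period_hi = 28,
                      period_step = 0.05) {
  s <- as_series(series)
  if (nrow(s) < 8) abort("need at least 8 observations for a periodogram.")
  periods <- seq(period_lo, period_hi, by = period_step)
  p <- drop(lsp_power_matrix(s$time_h, matrix(s$value), periods))
  out <- tibble(period_h = periods, power = p)
  attr(out, "peak_period_h") <- periods[which.max(p)]
  attr(out, "peak_power") <- max(p)
  class(out) <- c("lsp_spectrum", class(out))
  out
}

#' Lomb-Scargle permutation test for rhythmicity
#'
#' Tests the peak Lomb-Scargle power in a period band against a null obtained
#' by shuffling values across time points. The p-value is
#' \eqn{(1 + \#\{P^*_{max} \ge P_{max}\})/(n_{perm} + 1)}, so the smallest
#' attainable p is \eqn{1/(n_{perm}+1)}.
#'
#' @inheritParams lsp_power
#' @param n_perm Number of permutations (default 2000).
#' @param seed Integer seed for the permutation stream.
#' @return A one-row rhythm-result tibble (`method`, `p_value`, `statistic` =
#'   peak power, `period_h`, `phase_h`, `amplitude`, `n_perm`).
#' @export
lsp_permutation_test <- function(series, period_lo = 20, period_hi = 28,
                                 n_perm = 2000, seed = 1,
                                 period_step = 0.05) {
  if (n_perm < 1) abort("`n_perm` must be at least 1.")
  s <- as_series(series)
  if (nrow(s) < 8) abort("need at least 8 observations.")
  periods <- seq(period_lo, period_hi, by = period_step)
  obs <- lsp_power_matrix(s$time_h, matrix(s$value), periods)
  peak_i <- which.max(obs)
  peak <- max(obs)
  null_max <- with_seed(seed, {
    n <- nrow(s)
    Y <- vapply(seq_len(n_perm), function(i) s$value[sample.int(n)],
                numeric(n))
    apply(lsp_power_matrix(s$time_h, Y, periods), 2, max)
  })
  pa <- cosinor_phase_amp(s$time_h, s$value, periods[peak_i])
  rhythm_result("lsp",
                p_value = (1 + sum(null_max >= peak)) / (n_perm + 1),
                statistic = peak, period_h = periods[peak_i],
                phase_h = pa$phase_h, amplitude = pa$amplitude,
                n_perm = as.integer(n_perm))
}

#' Replicate-aware Lomb-Scargle permutation test
#'
#' For designs with replicate measurements per time point: the observed
#' statistic is the peak Lomb-Scargle power of the per-timepoint mean series,
#' and the permutation null shuffles *all* individual replicate values
#' jointly across the design before re-computing the means (e.g. all 49
#' values of a 13-timepoint, 3-4-replicate design are rearranged at each
#' permutation). With a single replicate everywhere this reduces exactly to
#' [lsp_permutation_test()].
#'
#' @param series Data frame with columns `time_h` and `value`; several rows
#'   may share a `time_h` (the replicates; ragged designs allowed).
#' @inheritParams lsp_permutation_test
#' @return A one-row rhythm-result tibble.
#' @export
lsp_replicate_permutation_test <- function(series, period_lo = 20,
                                           period_hi = 28, n_perm = 2000,
                                           seed = 1, period_step = 0.05) {
  if (n_perm < 1) abort("`n_perm` must be at least 1.")
  s <- as_series(series)
  tp <- factor(s$time_h, levels = sort(unique(s$time_h)))
  if (nlevels(tp) < 8) abort("need at least 8 distinct time points.")
  counts <- as.vector(table(tp))
  t_mean <- as.numeric(levels(tp))
  periods <- seq(period_lo, period_hi, by = period_step)
  mean_obs <- as.vector(rowsum(s$value, tp) / counts)
  obs_mat <- lsp_power_matrix(t_mean, matrix(mean_obs), periods)
  peak_i <- which.max(obs_mat)
  peak <- max(obs_mat)
  null_max <- with_seed(seed, {
    n <- nrow(s)
    V <- vapply(seq_len(n_perm), function(i) s$value[sample.int(n)],
                numeric(n))
    M <- rowsum(V, tp) / counts
    apply(lsp_power_matrix(t_mean, M, periods), 2, max)
  })
  pa <- cosinor_phase_amp(t_mean, mean_obs, periods[peak_i])
  rhythm_result("lsp_replicate",
                p_value = (1 + sum(null_max >= peak)) / (n_perm + 1),
                statistic = peak, period_h = periods[peak_i],
                phase_h = pa$phase_h, amplitude = pa$amplitude,
                n_perm = as.integer(n_perm))
}
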