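#' Continuous Morlet wavelet spectrum of an hourly series
#'
#' Continuous wavelet transform with a Morlet mother wavelet
#' (\eqn{\omega_0 = 6}) computed in Fourier space with zero padding; power is
#' \eqn{|W|^2}. The period grid is log-spaced between `period_lo` and
#' `period_hi` hours (scales converted with the standard Morlet
#' Fourier factor \eqn{4\pi/(\omega_0 + \sqrt{2 + \omega_0^2})}). Series
#' shorter than twice the largest period are allowed but flagged, since the
#' long-period end then sits inside the cone of influence.
#'
#' @param series Data frame with `time_h` (uniform hourly grid) and `value`.
#' @param period_lo,period_hi Smallest and largest period, hours (defaults 2
#'   and 36).
#' @param n_periods Number of log-spaced periods (>= 40).
#' @param label Series label carried into clustering.
#' @return An object of class `wavelet_spectrum`: list with `label`, `times`,
#'   `periods`, `wave` (complex transform, period x time), `power`
#'   (\eqn{|W|^2}) and `coi_flagged`.
#' @export
wavelet_spectrum <- function(series, period_lo = 2, period_hi = 36,
                             n_periods = 48, label = "series") {
  s <- as_series(series)
  n <- nrow(s)
  dt <- diff(s$time_h[1:2])
  if (n < 2 * period_lo / dt) abort("series too short for the smallest period.")
  if (n_periods < 40) abort("use at least 40 period grid points.")
  omega0 <- 6
  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  periods <- exp(seq(log(period_lo), log(period_hi), length.out = n_periods))
  scales <- periods / fourier_factor
  y <- s$value - mean(s$value)
  npad <- 2^ceiling(log2(n))
  yhat <- fft(c(y, rep(0, npad - n)))
  k <- 0:(npad - 1)
  omega <- ifelse(k <= npad / 2, 2 * pi * k / (npad * dt),
                  -2 * pi * (npad - k) / (npad * dt))
  W <- matrix(0 + 0i, length(scales), n)
  for (j in seq_along(scales)) {
    s_j <- scales[j]
    psi <- sqrt(2 * pi * s_j / dt) * pi^(-1 / 4) *
      exp(-((s_j * omega - omega0)^2) / 2) * (omega > 0)
    w <- fft(yhat * psi, inverse = TRUE) / npad
    W[j, ] <- w[seq_len(n)]
  }
  structure(
    list(label = label, times = s$time_h, periods = periods,
         wave = W, power = Mod(W)^2,
         coi_flagged = n * dt < 2 * period_hi),
    class = "wavelet_spectrum"
  )
}

#' Distance matrix between wavelet spectra
#'
#' Pairwise dissimilarity between wavelet decompositions on a shared
#' time/period grid. The default metric (`on = "transform"`) scales each
#' complex transform to unit total power and takes the Frobenius norm of the
#' difference; it is sensitive to both spectral content and the timing of
#' the oscillation, so phase-inverted rhythms are far apart. The
#' `on = "power"` alternative compares unit-normalised power matrices
#' \eqn{|W|^2} and is blind to phase. Constant series (zero total power)
#' keep their zero matrix. The metric used is recorded in the `"metric"`
#' attribute.
#'
#' @param spectra List of [wavelet_spectrum()] objects on identical grids.
#' @param on `"transform"` (default) or `"power"`.
#' @return Symmetric distance matrix with zero diagonal, labelled by the
#'   spectra's labels.
#' @export
wavelet_distance_matrix <- function(spectra, on = c("transform", "power")) {
  on <- match.arg(on)
  stopifnot(length(spectra) >= 2)
  ref_p <- spectra[[1]]$periods; ref_t <- spectra[[1]]$times
  mats <- lapply(spectra, function(sp) {
    stopifnot(inherits(sp, "wavelet_spectrum"))
    if (!isTRUE(all.equal(sp$periods, ref_p)) ||
        !isTRUE(all.equal(sp$times, ref_t))) {
      abort("spectra are not on a common time/period grid.")
    }
    tot <- sum(sp$power)
    if (on == "transform") {
      if (tot > 0) sp$wave / sqrt(tot) else sp$wave
    } else {
      if (tot > 0) sp$power / tot else sp$power
    }
  })
  k <- length(mats)
  D <- matrix(0, k, k,
              dimnames = list(vapply(spectra, `[[`, character(1), "label"),
                              vapply(spectra, `[[`, character(1), "label")))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      D[i, j] <- D[j, i] <- sqrt(sum(Mod(mats[[i]] - mats[[j]])^2))
    }
  }
  attr(D, "metric") <- on
  D
}

#' Principal-component embedding of a distance matrix
#'
#' Treats each row of a symmetric distance matrix as a feature vector,
#' centers the columns (no scaling) and rotates onto principal components;
#' all components with eigenvalue above `1e-10` are retained.
#'
#' @param D Square symmetric distance matrix.
#' @return Matrix of coordinates (series x components) with the retained
#'   eigenvalues as attribute `"eigenvalues"`.
#' @export
pca_embed <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || !isTRUE(all.equal(D, t(D), tolerance = 1e-8))) {
    abort("input must be a square symmetric matrix.")
  }
  pc <- prcomp(D, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  keep <- which(ev > 1e-10)
  if (length(keep) == 0) keep <- 1L
  out <- pc$x[, keep, drop = FALSE]
  rownames(out) <- rownames(D)
  attr(out, "eigenvalues") <- ev[keep]
  out
}
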