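# Shared fixtures, generated in code.

cosine_series <- function(times, amplitude = 1, phase_h = 18, period = 24,
                          mesor = 0, sd = 0) {
  tibble::tibble(
    time_h = times,
    value = mesor + amplitude * cos(2 * pi * (times - phase_h) / period) +
      (if (sd > 0) rnorm(length(times), 0, sd) else 0)
  )
}

# Build a one-animal track whose per-frame speeds (cm/s) are exactly `speeds`,
# moving along the x axis. First frame speed is 0 by convention.
track_from_speeds <- function(speeds, fps = 2, animal_id = "a") {
  stopifnot(speeds[1] == 0)
  x <- cumsum(speeds / fps)
  tr <- tibble::tibble(animal_id = animal_id,
                       t = (seq_along(speeds) - 1) / fps,
                       x = x, y = 0, likelihood = 1)
  attr(tr, "fps") <- fps
  attr(tr, "zt_offset_h") <- 0
  tr
}

# Brute-force bout detection: enumerate all maximal runs of frames with
# speed >= v_min and keep those lasting >= min_dur_s.
oracle_moving_mask <- function(speeds, fps, v_min = 0.03, min_dur_s = 3) {
  n <- length(speeds)
  mask <- rep(FALSE, n)
  i <- 1
  while (i <= n) {
    if (speeds[i] >= v_min - 1e-9) {
      j <- i
      while (j < n && speeds[j + 1] >= v_min - 1e-9) j <- j + 1
      if ((j - i + 1) / fps >= min_dur_s) mask[i:j] <- TRUE
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  mask
}

# Minimal activity-series tibble for binning/contrast tests.
activity_series <- function(zt_h, distance_cm,
                            pct_active = rep(0, length(zt_h)),
                            animal_id = "a") {
  mx <- max(distance_cm)
  tibble::tibble(animal_id = animal_id, zt_h = zt_h,
                 distance_cm = distance_cm, pct_active = pct_active,
                 norm_distance = if (mx > 0) distance_cm / mx else 0 * distance_cm)
}

# Kendall tau by explicit pair counting (tau-b style numerator/denominator).
oracle_kendall <- function(x, y) {
  n <- length(x)
  num <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
      num <- num + sx * sy
      if (sx != 0) tx <- tx + 1
      if (sy != 0) ty <- ty + 1
    }
  }
  num / sqrt(tx * ty)
}
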