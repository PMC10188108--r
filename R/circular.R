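#' Circular summary of a phase sample on the 24-hour clock
#'
#' Computes the vector mean direction and resultant length of phases mapped
#' onto angles \eqn{2\pi \cdot \mathrm{phase}/24}; the circular variance is
#' \eqn{1 - R}.
#'
#' @param phases Numeric vector of phases, hours (wrapped mod 24).
#' @param period Clock period, hours.
#' @return A one-row tibble: `n`, `mean_h`, `resultant_length`,
#'   `circular_variance`.
#' @examples
#' circular_summary(c(17, 19))
#' @export
circular_summary <- function(phases, period = 24) {
  if (length(phases) < 1) abort("need at least one phase.")
  a <- hours_to_rad(phases, period)
  C <- mean(cos(a)); S <- mean(sin(a))
  R <- sqrt(C^2 + S^2)
  tibble(n = length(phases),
         mean_h = if (R > .Machine$double.eps) rad_to_hours(atan2(S, C), period) else NA_real_,
         resultant_length = R,
         circular_variance = 1 - R)
}

#' Rayleigh test for circular uniformity
#'
#' Tests a phase sample against circular uniformity using \eqn{Z = n
#' \bar{R}^2} with a finite-sample series correction; for very small samples
#' a Monte-Carlo null is available (and used by default for n < 10).
#'
#' @param phases Phases in hours.
#' @param period Clock period (default 24).
#' @param method `"auto"` (Monte-Carlo for n < 10, approximation otherwise),
#'   `"approximation"`, or `"monte_carlo"`.
#' @param n_mc Draws for the Monte-Carlo null.
#' @param seed Seed for the Monte-Carlo null.
#' @return A one-row tibble: `n`, `resultant_length`, `statistic` (Z),
#'   `p_value`, `method`.
#' @export
rayleigh_test <- function(phases, period = 24, method = c("auto",
                          "approximation", "monte_carlo"),
                          n_mc = 1e5, seed = 1) {
  method <- match.arg(method)
  n <- length(phases)
  if (n < 3) abort("need at least 3 phases.")
  a <- hours_to_rad(phases, period)
  Rbar <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  Z <- n * Rbar^2
  if (method == "auto") method <- if (n < 10) "monte_carlo" else "approximation"
  p <- if (method == "approximation") {
    # Zar's series approximation
    pv <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                       (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
    min(max(pv, 0), 1)
  } else {
    with_seed(seed, {
      u <- matrix(runif(n_mc * n, 0, 2 * pi), n_mc, n)
      Zs <- n * (rowMeans(cos(u))^2 + rowMeans(sin(u))^2)
      (1 + sum(Zs >= Z)) / (n_mc + 1)
    })
  }
  tibble(n = n, resultant_length = Rbar, statistic = Z, p_value = p,
         method = method)
}

# Watson's two-sample U^2 on the circle (ties grouped).
watson_u2_stat <- function(a1, a2) {
  n <- length(a1); m <- length(a2); N <- n + m
  vals <- sort(unique(c(a1, a2)))
  c1 <- vapply(vals, function(v) sum(a1 <= v), numeric(1)) / n
  c2 <- vapply(vals, function(v) sum(a2 <= v), numeric(1)) / m
  k <- vapply(vals, function(v) sum(a1 == v) + sum(a2 == v), numeric(1))
  d <- c1 - c2
  (n * m / N^2) * (sum(k * d^2) - sum(k * d)^2 / N)
}

#' Bootstrapped Watson two-sample test for circular distributions
#'
#' Watson's \eqn{U^2} statistic between two phase samples, with significance
#' assessed by pooled-resampling bootstrap (samples of the original sizes are
#' redrawn with replacement from the pooled phases; default 9999 bootstraps).
#'
#' @param phases1,phases2 Phase samples in hours (each n >= 4).
#' @param period Clock period.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Seed for the bootstrap stream.
#' @return One-row tibble: `statistic` (observed \eqn{U^2}), `p_value`,
#'   `n1`, `n2`, `n_boot`.
#' @export
watson_two_sample <- function(phases1, phases2, period = 24, n_boot = 9999,
                              seed = 1) {
  if (n_boot < 1) abort("`n_boot` must be at least 1.")
  if (length(phases1) < 4 || length(phases2) < 4) {
    abort("both samples need at least 4 phases.")
  }
  a1 <- hours_to_rad(phases1, period); a2 <- hours_to_rad(phases2, period)
  obs <- watson_u2_stat(a1, a2)
  pooled <- c(a1, a2)
  n <- length(a1); m <- length(a2)
  null <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      watson_u2_stat(sample(pooled, n, replace = TRUE),
                     sample(pooled, m, replace = TRUE))
    }, numeric(1))
  })
  tibble(statistic = obs,
         p_value = (1 + sum(null >= obs)) / (n_boot + 1),
         n1 = n, n2 = m, n_boot = as.integer(n_boot))
}

#' Monte-Carlo homogeneity test for two circular samples
#'
#' Tests whether two phase samples are drawn from the same circular
#' distribution. The statistic sums the squared distances between the
#' samples' first and second trigonometric moment vectors (the second moment
#' makes the test sensitive to shifts of bimodal, antipodally symmetric
#' distributions whose first resultant vanishes), scaled by
#' \eqn{n_1 n_2 / N}; the null is generated by Monte-Carlo permutation of
#' the pooled sample (default 10,000 replications).
#'
#' @param phases1,phases2 Phase samples in hours.
#' @param period Clock period.
#' @param n_mc Monte-Carlo replications.
#' @param seed Seed.
#' @return One-row tibble: `statistic`, `p_value`, `n1`, `n2`, `n_mc`.
#' @export
circular_homogeneity_test <- function(phases1, phases2, period = 24,
                                      n_mc = 10000, seed = 1) {
  a1 <- hours_to_rad(phases1, period); a2 <- hours_to_rad(phases2, period)
  n1 <- length(a1); n2 <- length(a2); N <- n1 + n2
  tstat <- function(x1, x2) {
    (n1 * n2 / N) * ((mean(cos(x1)) - mean(cos(x2)))^2 +
                       (mean(sin(x1)) - mean(sin(x2)))^2 +
                       (mean(cos(2 * x1)) - mean(cos(2 * x2)))^2 +
                       (mean(sin(2 * x1)) - mean(sin(2 * x2)))^2)
  }
  obs <- tstat(a1, a2)
  pooled <- c(a1, a2)
  null <- with_seed(seed, {
    vapply(seq_len(n_mc), function(i) {
      idx <- sample.int(N, n1)
      tstat(pooled[idx], pooled[-idx])
    }, numeric(1))
  })
  tibble(statistic = obs, p_value = (1 + sum(null >= obs)) / (n_mc + 1),
         n1 = n1, n2 = n2, n_mc = as.integer(n_mc))
}

#' Attribute individual phases to light-driven or temperature-driven rhythms
#'
#' For animals entrained by a light cycle and a temperature cycle delayed by
#' `offset_h`, compares each individual's activity phase with the expected
#' phase of a light-entrained rhythm (`expected_light_h`, default ZT18) and
#' of a temperature-entrained rhythm (`expected_light_h + offset_h` mod 24)
#' using circular distances, then applies a paired Wilcoxon signed-rank test
#' to decide which zeitgeber the phases track.
#'
#' @param phases Individual peak phases, hours.
#' @param offset_h Delay of the temperature cycle relative to light, hours
#'   (an even value in \[0, 12\]).
#' @param expected_light_h Expected phase of a purely light-entrained rhythm.
#' @param alpha Significance level for the verdict.
#' @return A list of class `phase_attribution`: `distances` tibble
#'   (`phase_h`, `d_light`, `d_temp`), `p_value`, `verdict` (one of
#'   `"light-closer"`, `"temp-closer"`, `"equidistant"`), expected phases.
#' @export
zeitgeber_phase_attribution <- function(phases, offset_h,
                                        expected_light_h = 18,
                                        alpha = 0.05) {
  if (length(phases) < 1) abort("empty phase sample.")
  if (offset_h < 0 || offset_h > 12 || offset_h %% 2 != 0) {
    abort("`offset_h` must be an even value in [0, 12].")
  }
  expected_temp_h <- wrap_hours(expected_light_h + offset_h)
  d_light <- circ_dist_hours(phases, expected_light_h)
  d_temp <- circ_dist_hours(phases, expected_temp_h)
  p <- tryCatch({
    if (all(d_light == d_temp)) 1 else
      suppressWarnings(wilcox.test(d_light, d_temp, paired = TRUE,
                                   exact = length(phases) <= 25)$p.value)
  }, error = function(e) 1)
  verdict <- if (p >= alpha) "equidistant" else if (mean(d_light) < mean(d_temp))
    "light-closer" else "temp-closer"
  structure(
    list(distances = tibble(phase_h = phases, d_light = d_light,
                            d_temp = d_temp),
         p_value = p, verdict = verdict,
         expected_light_h = expected_light_h,
         expected_temp_h = expected_temp_h),
    class = "phase_attribution"
  )
}

#' @export
print.phase_attribution <- function(x, ...) {
  cat(sprintf("Phase attribution: expected light %g h, temperature %g h\n",
              x$expected_light_h, x$expected_temp_h))
  cat(sprintf("  median d_light %.2f h, median d_temp %.2f h, p = %.3g -> %s\n",
              median(x$distances$d_light), median(x$distances$d_temp),
              x$p_value, x$verdict))
  invisible(x)
}

#' Align animals by their preferred half-period activity window
#'
#' Used when a zeitgeber with half the circadian period leaves individuals
#' split between two opposite 12-h activity windows: each animal is assigned
#' to the window (\[0,12) or \[12,24), hours mod 24) holding the larger total
#' activity, the second group's series are circularly shifted by 12 h, and
#' the mean profile and its Lomb-Scargle permutation test are recomputed on
#' the aligned set. Ties are deterministically assigned to \[0,12) and
#' flagged.
#'
#' @param series Stacked activity series (`animal_id`, `zt_h`,
#'   `norm_distance`) on a common hourly ZT grid spanning >= 48 h.
#' @param window_h Alignment window, hours (default 12).
#' @param period_lo,period_hi,n_perm,seed Passed to [lsp_permutation_test()]
#'   on the aligned mean.
#' @return A list of class `half_period_alignment`: `aligned_series`,
#'   `assignments` (tibble with `animal_id`, `window`, `shifted`, `tie`),
#'   `profile` (tibble `zt_h`, `mean`), `rhythm` (rhythm-result row).
#' @export
align_half_period <- function(series, window_h = 12, period_lo = 20,
                              period_hi = 28, n_perm = 200, seed = 1) {
  stopifnot(all(c("animal_id", "zt_h", "norm_distance") %in% names(series)))
  grid <- sort(unique(series$zt_h))
  if (diff(range(grid)) < 47) abort("series must cover at least 48 h.")
  per_animal <- split(series[order(series$animal_id, series$zt_h), ],
                      series$animal_id[order(series$animal_id, series$zt_h)])
  shift_bins <- round(window_h / diff(grid[1:2]))
  out <- purrr::map(per_animal, function(df) {
    if (!identical(df$zt_h, grid)) abort("animals are not on a common ZT grid.")
    in_first <- wrap_hours(df$zt_h) < window_h
    tot1 <- sum(df$norm_distance[in_first])
    tot2 <- sum(df$norm_distance[!in_first])
    tie <- isTRUE(all.equal(tot1, tot2))
    shifted <- !tie && tot2 > tot1
    v <- df$norm_distance
    if (shifted) {
      n <- length(v)
      v <- v[((seq_len(n) - 1 + shift_bins) %% n) + 1]
    }
    list(assign = tibble(animal_id = df$animal_id[1],
                         window = if (shifted) "second" else "first",
                         shifted = shifted, tie = tie),
         series = tibble(animal_id = df$animal_id[1], zt_h = grid,
                         norm_distance = v))
  })
  assignments <- purrr::map_dfr(out, "assign")
  aligned <- purrr::map_dfr(out, "series")
  profile <- aligned |>
    group_by(.data$zt_h) |>
    summarise(mean = mean(.data$norm_distance), .groups = "drop")
  rhythm <- lsp_permutation_test(
    tibble(time_h = profile$zt_h, value = profile$mean),
    period_lo = period_lo, period_hi = period_hi, n_perm = n_perm,
    seed = seed)
  structure(
    list(aligned_series = aligned, assignments = assignments,
         profile = profile, rhythm = rhythm),
    class = "half_period_alignment"
  )
}
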