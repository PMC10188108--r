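#' Empirical reference-waveform test for 24-hour rhythmicity
#'
#' A permutation-calibrated analogue of the empirical JTK approach: the series
#' is compared (Kendall's tau) against a set of reference 24-h cosines with
#' peak phases at `0 ... 23` h, the statistic is the maximum tau over
#' references, and significance comes from permuting the series against the
#' fixed reference set. Tests specifically for 24-h periods.
#'
#' @param series Data frame with `time_h`, `value` (>= 12 observations).
#' @param n_phase_refs Number of equally spaced reference phases (default 24).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A one-row rhythm-result tibble; `phase_h` is the best reference
#'   phase, `statistic` the maximal Kendall tau.
#' @export
empirical_jtk_24h <- function(series, n_phase_refs = 24, n_perm = 1000,
                              seed = 1) {
  s <- as_series(series)
  if (nrow(s) < 12) abort("need at least 12 observations.")
  if (n_perm < 1) abort("`n_perm` must be at least 1.")
  phases <- seq(0, 24, length.out = n_phase_refs + 1)[seq_len(n_phase_refs)]
  refs <- vapply(phases, function(p) cos(2 * pi * (s$time_h - p) / 24),
                 numeric(nrow(s)))
  max_tau <- function(y) {
    if (sd(y) == 0) return(0)
    max(suppressWarnings(cor(y, refs, method = "kendall")), na.rm = TRUE)
  }
  obs_all <- if (sd(s$value) == 0) rep(0, n_phase_refs) else
    drop(suppressWarnings(cor(s$value, refs, method = "kendall")))
  obs <- max(obs_all)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) max_tau(sample(s$value)), numeric(1))
  })
  pa <- cosinor_phase_amp(s$time_h, s$value, 24)
  rhythm_result("ejtk",
                p_value = (1 + sum(null >= obs)) / (n_perm + 1),
                statistic = obs, period_h = 24,
                phase_h = phases[which.max(obs_all)],
                amplitude = pa$amplitude, n_perm = as.integer(n_perm))
}

#' Multi-harmonic least-squares period and phase estimation
#'
#' Curve-fitting period estimation: for every candidate period on a fine
#' grid, truncated Fourier series with 1 to `n_harmonics` harmonics are
#' fitted by least squares and scored by BIC, so higher harmonics are kept
#' only when the waveform supports them (a pure cosine is not forced to
#' carry noise-fitting harmonics that would degrade the phase estimate).
#' The period minimising the BIC wins (ties go to the smaller period).
#' Phase is the time of the fitted waveform's maximum over one period,
#' amplitude is half its peak-to-trough range.
#'
#' @param series Data frame with `time_h`, `value`.
#' @param period_lo,period_hi Period search bounds, hours.
#' @param n_harmonics Maximum number of Fourier harmonics (default 3).
#' @param period_step Period grid resolution, hours (default 0.02).
#' @return A one-row rhythm-result tibble; `statistic` is the fit
#'   \eqn{R^2}. The harmonic coefficients of the winning fit (padded with
#'   zeros up to `n_harmonics`) are attached as attribute `"coefficients"`.
#' @export
mfourfit_estimate <- function(series, period_lo = 20, period_hi = 28,
                              n_harmonics = 3, period_step = 0.02) {
  s <- as_series(series)
  n <- nrow(s)
  if (n < 2 * (2 * n_harmonics + 1)) {
    abort("too few observations for the requested number of harmonics.")
  }
  span <- diff(range(s$time_h))
  if (period_lo <= 0 || period_hi > 2 * span) {
    abort("period range must lie in (0, 2 * span].")
  }
  periods <- seq(period_lo, period_hi, by = period_step)
  y <- s$value
  tss <- sum((y - mean(y))^2)
  best <- list(bic = Inf, k = NA_integer_, h = NA_integer_,
               coef = NULL, rss = Inf)
  for (k in seq_along(periods)) {
    w <- 2 * pi / periods[k]
    X <- matrix(1, n, 1)
    for (h in seq_len(n_harmonics)) {
      X <- cbind(X, cos(h * w * s$time_h), sin(h * w * s$time_h))
      fit <- .lm.fit(X, y)
      rss <- sum(fit$residuals^2)
      bic <- n * log(max(rss / n, 1e-300)) + (2 * h + 1) * log(n)
      if (bic < best$bic - 1e-9) {
        best <- list(bic = bic, k = k, h = h, coef = fit$coefficients,
                     rss = rss)
      }
    }
  }
  tau <- periods[best$k]
  coef_full <- c(best$coef, rep(0, 2 * n_harmonics + 1 - length(best$coef)))
  tg <- seq(0, tau, by = 0.01)
  w <- 2 * pi / tau
  Xg <- cbind(1, do.call(cbind, lapply(seq_len(n_harmonics), function(h)
    cbind(cos(h * w * tg), sin(h * w * tg)))))
  wave <- drop(Xg %*% coef_full)
  res <- rhythm_result("mfourfit",
                       statistic = if (tss > 0) 1 - best$rss / tss else 0,
                       period_h = tau,
                       phase_h = wrap_hours(tg[which.max(wave)], tau),
                       amplitude = (max(wave) - min(wave)) / 2)
  attr(res, "coefficients") <- coef_full
  res
}

# --- Umbrella / Jonckheere-Terpstra machinery ------------------------------

# Mann-Whitney-type count for an ordered pair of groups: #{x < y} + 0.5 ties.
mw_count <- function(x, y) {
  sum(outer(x, y, `<`)) + 0.5 * sum(outer(x, y, `==`))
}

# Exact first and second permutation-null moments of a generalized
# Jonckheere statistic U = sum over ordered group pairs (a, b) in `pairs`
# of W_ab = sum_{i in a, j in b} h(x_i, x_j), h = I(x < y) + 0.5 I(x == y),
# when the pooled values are randomly assigned to positions. Ties and the
# covariance between overlapping arms are handled exactly.
jt_moments_env <- function(values) {
  N <- length(values)
  H <- outer(values, values, `<`) + 0.5 * outer(values, values, `==`)
  diag(H) <- 0
  a_i <- rowSums(H)            # h(x_i, .) totals
  b_i <- colSums(H)
  S0 <- sum(H^2)
  S1 <- N * (N - 1) / 2
  T5 <- sum(H * t(H))          # sum_{i != j} h_ij h_ji (tie mass)
  T1 <- sum(a_i^2) - S0
  T2 <- sum(b_i^2) - S0
  T3 <- sum(a_i * b_i) - T5
  T4 <- S1^2 - S0 - T1 - T2 - 2 * T3 - T5
  list(N = N,
       q0 = S0 / (N * (N - 1)),
       q1 = T1 / (N * (N - 1) * (N - 2)),
       q2 = T2 / (N * (N - 1) * (N - 2)),
       q3 = T3 / (N * (N - 1) * (N - 2)),
       q5 = T5 / (N * (N - 1)),
       q4 = if (N > 3) T4 / (N * (N - 1) * (N - 2) * (N - 3)) else 0)
}

# E and Var of U for a pair set, given group sizes ns and the moments above.
jt_pairset_moments <- function(pairs, ns, mom) {
  np <- nrow(pairs)
  E <- 0.5 * sum(ns[pairs[, 1]] * ns[pairs[, 2]])
  V <- 0
  for (u in seq_len(np)) {
    a <- pairs[u, 1]; b <- pairs[u, 2]
    for (v in seq_len(np)) {
      c_ <- pairs[v, 1]; d <- pairs[v, 2]
      na <- ns[a]; nb <- ns[b]; nc <- ns[c_]; nd <- ns[d]
      n_q0 <- if (a == c_ && b == d) na * nb else 0
      n_q1 <- if (a == c_) na * (nb * nd - (b == d) * nb) else 0
      n_q2 <- if (b == d) nb * (na * nc - (a == c_) * na) else 0
      n_q5 <- if (a == d && b == c_) na * nb else 0
      n_q3 <- (if (b == c_) nb * (na * nd - (a == d) * na) else 0) +
        (if (a == d) na * (nb * nc - (b == c_) * nb) else 0)
      n_q4 <- na * nb * nc * nd - n_q0 - n_q1 - n_q2 - n_q5 - n_q3
      V <- V + n_q0 * mom$q0 + n_q1 * mom$q1 + n_q2 * mom$q2 +
        n_q5 * mom$q5 + n_q3 * mom$q3 + n_q4 * mom$q4 -
        na * nb * nc * nd * 0.25
    }
  }
  list(E = E, V = max(V, 0))
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# Exact permutation null of U over a position-pair list, for tiny samples.
jt_exact_pvalue <- function(values, gidx, pairs, U_obs) {
  N <- length(values)
  H <- outer(values, values, `<`) + 0.5 * outer(values, values, `==`)
  pos_pairs <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(u) {
    expand.grid(i = which(gidx == pairs[u, 1]),
                j = which(gidx == pairs[u, 2]))
  }))
  perms <- all_permutations(N)
  U_null <- rep(0, nrow(perms))
  for (r in seq_len(nrow(pos_pairs))) {
    U_null <- U_null + H[cbind(perms[, pos_pairs$i[r]],
                               perms[, pos_pairs$j[r]])]
  }
  mean(U_null >= U_obs - 1e-9)
}

# Shared Monte-Carlo null tables for the umbrella statistic. For
# continuous data the statistic depends on the values only through their
# ranks, so the per-shape null distribution is a function of the design
# (group sizes and shape pair sets) alone and can be simulated once and
# reused for every series measured on that design (e.g. all genes of a
# screen).
.umbrella_cache <- new.env(parent = emptyenv())

umbrella_rank_null <- function(gidx, n_shapes, pairsets, n_null, seed) {
  N <- length(gidx)
  k <- max(gidx)
  Z <- outer(gidx, seq_len(k), `==`) * 1
  S <- matrix(0, k * k, n_shapes)
  for (s in seq_len(n_shapes)) {
    idx <- (pairsets[[s]][, 2] - 1) * k + pairsets[[s]][, 1]
    S[idx, s] <- 1
  }
  with_seed(seed, {
    U <- matrix(0, n_null, n_shapes)
    for (b in seq_len(n_null)) {
      r <- sample.int(N)
      L <- outer(r, r, `<`) * 1
      Wm <- crossprod(Z, L %*% Z)
      U[b, ] <- as.vector(Wm) %*% S
    }
    U
  })
}

umbrella_null_table <- function(gidx, pairsets, n_null, seed) {
  key <- paste(c(gidx, length(pairsets), n_null, seed), collapse = ",")
  tab <- get0(key, envir = .umbrella_cache, inherits = FALSE)
  if (is.null(tab)) {
    U <- umbrella_rank_null(gidx, length(pairsets), pairsets, n_null, seed)
    # per-draw min over shapes of the per-shape empirical p, for the exact
    # single-step familywise (min-p) correction
    B <- nrow(U)
    pmat <- vapply(seq_len(ncol(U)), function(s) {
      (2 + B - rank(U[, s], ties.method = "min")) / (B + 1)
    }, numeric(B))
    # permutation moments are rank-based for tie-free data, hence shared
    # across all series on this design
    ns <- as.vector(table(gidx))
    mom <- jt_moments_env(seq_along(gidx))
    tab <- list(U_sorted = apply(U, 2, sort),
                minp_sorted = sort(apply(pmat, 1, min)),
                moments = lapply(pairsets, jt_pairset_moments, ns = ns,
                                 mom = mom))
    assign(key, tab, envir = .umbrella_cache)
  }
  tab
}

# Arm group lists for an umbrella shape: times in the closed circular
# interval [peak - rise, peak] ascending (rising arm) and [peak,
# peak + period - rise) descending toward the trough (falling arm, trough
# excluded so the trough-vs-peak comparison is not counted twice).
umbrella_arms <- function(times_mod, peak, rise, period) {
  ut <- sort(unique(times_mod))
  pos_from <- function(start, len, drop_last = FALSE) {
    rel <- wrap_hours(ut - start, period)
    sel <- rel <= len + 1e-9
    out <- ut[sel][order(rel[sel])]
    if (drop_last && length(out) > 1 &&
        abs(wrap_hours(out[length(out)] - start, period) - len) < 1e-9) {
      out <- out[-length(out)]
    }
    out
  }
  rising <- pos_from(wrap_hours(peak - rise, period), rise)
  falling <- pos_from(peak, period - rise, drop_last = TRUE)
  list(rising = rising, falling = falling)
}

# Ordered group-index pairs implied by one umbrella shape: every pair along
# the rising arm (ascending) plus every pair along the falling arm traversed
# from the trough side up to the peak.
umbrella_pairset <- function(pos_r, pos_f) {
  mk <- function(pos) {
    k <- length(pos)
    if (k < 2) return(NULL)
    do.call(rbind, lapply(seq_len(k - 1), function(i) {
      cbind(pos[i], pos[(i + 1):k])
    }))
  }
  rbind(mk(pos_r), mk(rev(pos_f)))
}

#' Umbrella-alternative rhythm screen for asymmetric waveforms
#'
#' Nonparametric rhythm detection in the spirit of rank-based umbrella
#' tests: every candidate waveform shape is a (peak time, rise length) pair,
#' with rise lengths in `asym_step_h` increments. Under a shape, values
#' pooled per time point (times taken mod `period`) should be non-decreasing
#' along the rising arm and non-increasing along the falling arm; the shape
#' statistic sums Jonckheere-Terpstra pair counts over both arms. Each
#' shape's p comes, by default, from a rank-permutation null simulated once
#' per design and shared across series on that design (`null = "rank"`; for
#' tie-free data the statistic is rank-based, so the table is universal); a
#' normal approximation with exact permutation-null mean and variance
#' (ties and arm overlap included) is available via `null = "normal"` and is
#' used automatically when the values contain ties. Pooled samples of at
#' most 8 observations are enumerated exactly instead. The reported raw p is
#' the minimum over shapes and the adjusted p applies a Bonferroni factor
#' equal to the number of shapes.
#'
#' @param series Data frame with `time_h`, `value`; replicates share a
#'   `time_h` and the two sampling cycles of a 48-h design fold together.
#' @param period Rhythm period, hours (default 24).
#' @param asym_step_h Increment of candidate rise lengths (default 4).
#' @param null `"rank"` (Monte-Carlo rank-permutation null, default) or
#'   `"normal"` (moment-matched normal approximation).
#' @param n_null Draws for the rank-permutation null table (default 20000).
#' @param null_seed Seed for the null table; fixed so results are
#'   reproducible and the table is shared across series.
#' @return A one-row rhythm-result tibble: `p_value` (min over shapes),
#'   `p_adj` (Bonferroni), `statistic` (best shape z), `phase_h` (peak time
#'   of the best shape), `amplitude` (half peak-to-trough of the
#'   per-timepoint means).
#' @export
umbrella_rhythm_test <- function(series, period = 24, asym_step_h = 4,
                                 null = c("rank", "normal"),
                                 n_null = 20000, null_seed = 1) {
  null <- match.arg(null)
  s <- as_series(series)
  tm <- wrap_hours(s$time_h, period)
  ut <- sort(unique(tm))
  if (length(ut) < 3) abort("need at least 3 distinct mod-period time points.")
  if (diff(range(s$time_h)) < period - 1e-9) {
    abort("time points must span at least one period.")
  }
  gfac <- factor(tm, levels = ut)
  groups_all <- split(s$value, gfac)
  gidx <- as.integer(gfac)
  k <- length(ut)
  ns <- lengths(groups_all)
  N <- sum(ns)
  # pairwise Mann-Whitney counts between all ordered timepoint groups,
  # shared across candidate shapes
  Wmat <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j) Wmat[i, j] <- mw_count(groups_all[[i]], groups_all[[j]])
  }
  rises <- seq(asym_step_h, period - asym_step_h, by = asym_step_h)
  shapes <- tidyr::expand_grid(peak = ut, rise = rises)
  pairsets <- purrr::pmap(shapes, function(peak, rise) {
    arms <- umbrella_arms(tm, peak, rise, period)
    umbrella_pairset(match(arms$rising, ut), match(arms$falling, ut))
  })
  has_ties <- anyDuplicated(s$value) > 0
  use_rank <- null == "rank" && !has_ties && N > 8
  null_tab <- if (use_rank) {
    umbrella_null_table(gidx, pairsets, n_null, null_seed)
  }
  mom <- if (!use_rank) jt_moments_env(s$value)
  n_shapes <- nrow(shapes)
  p_s <- rep(1, n_shapes); z_s <- rep(0, n_shapes)
  for (si in seq_len(n_shapes)) {
    pairs <- pairsets[[si]]
    if (is.null(pairs)) next
    U <- sum(Wmat[pairs])
    mo <- if (use_rank) null_tab$moments[[si]] else
      jt_pairset_moments(pairs, ns, mom)
    z_s[si] <- if (mo$V > 0) (U - mo$E) / sqrt(mo$V) else 0
    p_s[si] <- if (N <= 8) {
      jt_exact_pvalue(s$value, gidx, pairs, U)
    } else if (use_rank) {
      nn <- null_tab$U_sorted[, si]
      (1 + length(nn) - findInterval(U - 1e-9, nn)) / (length(nn) + 1)
    } else if (mo$V > 0) {
      pnorm(z_s[si], lower.tail = FALSE)
    } else 1
  }
  # ties in p (e.g. several shapes at the Monte-Carlo granularity floor)
  # break on the standardised statistic
  bi <- order(p_s, -z_s)[1]
  best <- list(p = p_s[bi], z = z_s[bi], peak = shapes$peak[bi])
  p_adj <- if (use_rank) {
    # exact single-step min-p familywise correction from the shared null
    mp <- null_tab$minp_sorted
    (1 + findInterval(best$p + 1e-12, mp)) / (length(mp) + 1)
  } else {
    min(1, best$p * nrow(shapes))
  }
  means <- vapply(groups_all, mean, numeric(1))
  out <- rhythm_result("umbrella",
                       p_value = best$p,
                       p_adj = p_adj,
                       statistic = best$z, period_h = period,
                       phase_h = best$peak,
                       amplitude = (max(means) - min(means)) / 2)
  attr(out, "n_shapes") <- n_shapes
  out
}
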