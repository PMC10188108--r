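#' Configuration for the locomotor-track simulator
#'
#' Bundles and validates the parameters of the synthetic pose-track generator.
#' Defaults emulate the study conditions the downstream pipeline was designed
#' for: groups of 24 animals filmed for 3 days at 2 frames per second, with a
#' nocturnal activity peak at ZT18 and strong (but not total) circadian
#' modulation of bout rate.
#'
#' Rhythmic animals start movement bouts according to an inhomogeneous Poisson
#' process with rate
#' \deqn{\lambda(t) = \lambda_0 (1 + m \cos(2\pi (t - \phi)/24))}
#' where \eqn{\lambda_0} is `bout_rate_base` (bouts/h), \eqn{m} is
#' `modulation_depth` and \eqn{\phi} is `peak_phase_h`. Arrhythmic animals use
#' the flat rate \eqn{\lambda_0}.
#'
#' @param seed Integer seed; the generator draws from its own seeded stream.
#' @param n_animals Number of animals.
#' @param duration_h Recording length in hours.
#' @param fps Frames per second (default 2).
#' @param rhythmic_fraction Fraction of animals given the rhythmic bout rate.
#' @param peak_phase_h Hour (mod 24) of peak bout rate.
#' @param bout_rate_base Baseline bout initiation rate, bouts per hour.
#' @param modulation_depth Relative amplitude of the bout-rate cosine, in \[0,1\].
#' @param bout_speed_cm_s Minimum within-bout speed, cm/s.
#' @param bout_duration_mean_s Mean of the exponential bout-duration law, seconds.
#' @param dropout_prob Per-frame probability of a low-likelihood (tracking
#'   dropout) frame; such frames get likelihood drawn below 0.90.
#' @param teleport_prob Per-frame probability of a jump artifact: the recorded
#'   position is displaced by more than 2 cm for that frame.
#' @param arena_cm Side of the square arena, cm; paths are folded into it.
#' @param zt_offset_h ZT hour at the start of the recording.
#'
#' @return An object of class `behavior_sim_config` (a named list).
#' @seealso [simulate_tracks()]
#' @export
behavior_sim_config <- function(seed,
                                n_animals = 24,
                                duration_h = 72,
                                fps = 2,
                                rhythmic_fraction = 1,
                                peak_phase_h = 18,
                                bout_rate_base = 2,
                                modulation_depth = 0.8,
                                bout_speed_cm_s = 0.05,
                                bout_duration_mean_s = 30,
                                dropout_prob = 0.02,
                                teleport_prob = 0.001,
                                arena_cm = 3.5,
                                zt_offset_h = 0) {
  check_positive(duration_h, "duration_h")
  check_positive(fps, "fps")
  check_positive(bout_rate_base, "bout_rate_base")
  check_positive(bout_speed_cm_s, "bout_speed_cm_s")
  check_positive(bout_duration_mean_s, "bout_duration_mean_s")
  check_positive(arena_cm, "arena_cm")
  check_prob(rhythmic_fraction, "rhythmic_fraction")
  check_prob(modulation_depth, "modulation_depth")
  check_prob(dropout_prob, "dropout_prob")
  check_prob(teleport_prob, "teleport_prob")
  if (peak_phase_h < 0 || peak_phase_h >= 24) {
    abort("`peak_phase_h` must lie in [0, 24).",
          class = "zeitconflict_invalid_config")
  }
  if (n_animals < 1) {
    abort("`n_animals` must be at least 1.",
          class = "zeitconflict_invalid_config")
  }
  structure(
    list(seed = seed, n_animals = as.integer(n_animals),
         duration_h = duration_h, fps = fps,
         rhythmic_fraction = rhythmic_fraction, peak_phase_h = peak_phase_h,
         bout_rate_base = bout_rate_base, modulation_depth = modulation_depth,
         bout_speed_cm_s = bout_speed_cm_s,
         bout_duration_mean_s = bout_duration_mean_s,
         dropout_prob = dropout_prob, teleport_prob = teleport_prob,
         arena_cm = arena_cm, zt_offset_h = zt_offset_h),
    class = "behavior_sim_config"
  )
}

# Bout start times on [0, duration_h) from an inhomogeneous Poisson process,
# by thinning against the rate envelope lambda_max.
sim_bout_starts <- function(duration_h, rate_base, depth, peak_phase_h,
                            zt_offset_h) {
  lambda_max <- rate_base * (1 + depth)
  n_cand <- stats::rpois(1, lambda_max * duration_h)
  if (n_cand == 0) return(numeric(0))
  cand <- sort(runif(n_cand, 0, duration_h))
  lam <- rate_base *
    (1 + depth * cos(2 * pi * (cand + zt_offset_h - peak_phase_h) / 24))
  keep <- runif(n_cand) < lam / lambda_max
  cand[keep]
}

# Triangle-wave fold of positions into [0, L]; preserves step continuity.
fold_into <- function(p, L) {
  m <- p %% (2 * L)
  ifelse(m > L, 2 * L - m, m)
}

#' Simulate markerless-tracking pose output with known ground truth
#'
#' Generates per-animal frame-level tracks (time, x, y, tracking likelihood)
#' shaped like the single-bodypart output of a pose-estimation tool. Rhythmic
#' animals move in discrete bouts whose start times follow an inhomogeneous
#' Poisson process peaking at `peak_phase_h`; bout durations are exponential.
#' Within a bout the animal takes frame steps of at least
#' `bout_speed_cm_s / fps` cm in a persistent, slowly wandering direction;
#' outside bouts it is stationary. Tracking dropouts get likelihood below
#' 0.90, jump artifacts displace the recorded position by more than 2 cm.
#'
#' @param cfg A [behavior_sim_config()].
#' @return A list with elements
#'   * `tracks`: tibble with columns `animal_id`, `t` (s), `x`, `y` (cm),
#'     `likelihood`, plus attributes `fps` and `zt_offset_h`;
#'   * `truth`: tibble with `animal_id`, `is_rhythmic`, `peak_phase_h`;
#'   * `config`: the input configuration.
#' @examples
#' sim <- simulate_tracks(behavior_sim_config(seed = 1, n_animals = 2,
#'                                            duration_h = 2))
#' head(sim$tracks)
#' @export
simulate_tracks <- function(cfg) {
  stopifnot(inherits(cfg, "behavior_sim_config"))
  with_seed(cfg$seed, {
    n_frames <- round(cfg$duration_h * 3600 * cfg$fps)
    t_s <- (seq_len(n_frames) - 1) / cfg$fps
    t_h <- t_s / 3600
    n_rhy <- round(cfg$rhythmic_fraction * cfg$n_animals)
    is_rhy <- rep(FALSE, cfg$n_animals)
    if (n_rhy > 0) is_rhy[sample.int(cfg$n_animals, n_rhy)] <- TRUE

    tracks <- purrr::map(seq_len(cfg$n_animals), function(a) {
      depth <- if (is_rhy[a]) cfg$modulation_depth else 0
      starts <- sim_bout_starts(cfg$duration_h, cfg$bout_rate_base, depth,
                                cfg$peak_phase_h, cfg$zt_offset_h)
      durs <- rexp(length(starts), rate = 3600 / cfg$bout_duration_mean_s)
      moving <- rep(FALSE, n_frames)
      bout_id <- rep(NA_integer_, n_frames)
      for (b in seq_along(starts)) {
        idx <- which(t_h >= starts[b] & t_h < starts[b] + durs[b])
        moving[idx] <- TRUE
        bout_id[idx] <- b
      }
      headings <- runif(max(1, length(starts)), 0, 2 * pi)
      speed <- runif(n_frames, 1, 1.5) * cfg$bout_speed_cm_s / cfg$fps
      ang <- ifelse(moving, headings[pmax(bout_id, 1L)], 0) +
        rnorm(n_frames, 0, 0.3)
      dx <- ifelse(moving, speed * cos(ang), 0)
      dy <- ifelse(moving, speed * sin(ang), 0)
      x0 <- runif(2, 0, cfg$arena_cm)
      x <- fold_into(x0[1] + cumsum(dx), cfg$arena_cm)
      y <- fold_into(x0[2] + cumsum(dy), cfg$arena_cm)

      lik <- runif(n_frames, 0.95, 1.0)
      drop <- runif(n_frames) < cfg$dropout_prob
      lik[drop] <- runif(sum(drop), 0, 0.899)
      tele <- runif(n_frames) < cfg$teleport_prob
      if (any(tele)) {
        r <- runif(sum(tele), 2.2, 4)
        th <- runif(sum(tele), 0, 2 * pi)
        x[tele] <- x[tele] + r * cos(th)
        y[tele] <- y[tele] + r * sin(th)
      }
      tibble(animal_id = sprintf("animal_%02d", a), t = t_s,
             x = x, y = y, likelihood = lik)
    })
    tracks <- bind_rows(tracks)
    attr(tracks, "fps") <- cfg$fps
    attr(tracks, "zt_offset_h") <- cfg$zt_offset_h
    truth <- tibble(
      animal_id = sprintf("animal_%02d", seq_len(cfg$n_animals)),
      is_rhythmic = is_rhy,
      peak_phase_h = ifelse(is_rhy, cfg$peak_phase_h, NA_real_)
    )
    list(tracks = tracks, truth = truth, config = cfg)
  })
}

#' Configuration for the rhythmic count-matrix simulator
#'
#' Parameters of the negative-binomial expression generator. Defaults emulate
#' a circadian RNA-seq design: 13 time points every 4 h over 48 h, three
#' replicates, two conditions (aligned zeitgebers vs sensory conflict where
#' the temperature cycle is delayed 12 h relative to light).
#'
#' Gene \eqn{g} has mean \eqn{\mu_g(t) = \exp(m_g + a_g \cos(2\pi (t -
#' \phi_g)/24))} scaled by a per-sample library-size factor; counts are
#' negative binomial with the given dispersion. Rhythmic genes draw
#' \eqn{\phi_g} from a von Mises distribution; `shift_fraction` of the shared
#' rhythmic genes have their condition-B phase displaced by +12 h, mirroring
#' genes that track a temperature cycle delayed 12 h against the light cycle.
#' `specific_fraction` of the rhythmic genes are rhythmic in only one
#' condition (split evenly), with \eqn{a_g = 0} in the other.
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes.
#' @param n_timepoints Number of time points (default 13).
#' @param timestep_h Sampling interval, hours (default 4). The design must
#'   span at least 48 h.
#' @param n_replicates Replicates per time point (default 3).
#' @param conditions Two condition labels.
#' @param rhythmic_fraction Fraction of genes rhythmic in at least one condition.
#' @param log_mean_range Range of baseline log-mean \eqn{m_g} (natural log).
#' @param amplitude_range Range of the log-scale amplitude \eqn{a_g}
#'   (\eqn{a_g = \log(2)/2} gives a 2-fold peak-to-trough ratio).
#' @param dispersion Negative-binomial dispersion (size = 1/dispersion).
#' @param phase_mu_h,phase_kappa Circular mean (hours) and concentration of
#'   the phase distribution; recycled across conditions.
#' @param shift_fraction Fraction of shared rhythmic genes whose condition-B
#'   phase equals the condition-A phase + 12 h.
#' @param specific_fraction Fraction of rhythmic genes rhythmic in only one
#'   condition, split evenly between the two.
#' @param library_size_range Range of per-sample library scaling factors.
#'
#' @return An object of class `expression_sim_config`.
#' @seealso [simulate_expression()]
#' @export
expression_sim_config <- function(seed,
                                  n_genes = 1000,
                                  n_timepoints = 13,
                                  timestep_h = 4,
                                  n_replicates = 3,
                                  conditions = c("Aligned", "SC"),
                                  rhythmic_fraction = 0.3,
                                  log_mean_range = c(log(50), log(500)),
                                  amplitude_range = c(log(2) / 2, log(2)),
                                  dispersion = 0.1,
                                  phase_mu_h = 18,
                                  phase_kappa = 1,
                                  shift_fraction = 0.58,
                                  specific_fraction = 0,
                                  library_size_range = c(0.8, 1.25)) {
  check_positive(dispersion, "dispersion")
  check_prob(rhythmic_fraction, "rhythmic_fraction")
  check_prob(shift_fraction, "shift_fraction")
  check_prob(specific_fraction, "specific_fraction")
  if (length(conditions) != 2) {
    abort("`conditions` must give exactly two labels.",
          class = "zeitconflict_invalid_config")
  }
  if ((n_timepoints - 1) * timestep_h < 48) {
    abort("the design must span at least 48 h.",
          class = "zeitconflict_invalid_config")
  }
  structure(
    list(seed = seed, n_genes = as.integer(n_genes),
         n_timepoints = as.integer(n_timepoints), timestep_h = timestep_h,
         n_replicates = as.integer(n_replicates), conditions = conditions,
         rhythmic_fraction = rhythmic_fraction,
         log_mean_range = log_mean_range, amplitude_range = amplitude_range,
         dispersion = dispersion,
         phase_mu_h = rep_len(phase_mu_h, 2),
         phase_kappa = rep_len(phase_kappa, 2),
         shift_fraction = shift_fraction,
         specific_fraction = specific_fraction,
         library_size_range = library_size_range),
    class = "expression_sim_config"
  )
}

#' Simulate a rhythmic negative-binomial count matrix with ground truth
#'
#' @param cfg An [expression_sim_config()].
#' @return A list with
#'   * `counts`: integer matrix, genes x samples;
#'   * `design`: tibble (`sample_id`, `condition`, `time_h`, `zt_h`,
#'     `replicate`, `lib_scaler`);
#'   * `truth`: tibble per gene (`gene_id`, `class`, `is_rhythmic`,
#'     `rhythmic_A`/`rhythmic_B`, `phase_A`/`phase_B`, `amplitude`,
#'     `log_mean`, `shifted_12h`);
#'   * `mu`: the noise-free mean matrix (before library scaling);
#'   * `config`.
#' @examples
#' sim <- simulate_expression(expression_sim_config(seed = 1, n_genes = 50))
#' dim(sim$counts)
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "expression_sim_config"))
  with_seed(cfg$seed, {
    ng <- cfg$n_genes
    gene_id <- sprintf("gene_%04d", seq_len(ng))

    n_rhy <- round(cfg$rhythmic_fraction * ng)
    rhy_idx <- if (n_rhy > 0) sample.int(ng, n_rhy) else integer(0)
    n_spec <- round(cfg$specific_fraction * n_rhy)
    n_spec_a <- n_spec %/% 2
    n_spec_b <- n_spec - n_spec_a
    spec_a <- head(rhy_idx, n_spec_a)
    spec_b <- head(setdiff(rhy_idx, spec_a), n_spec_b)
    shared <- setdiff(rhy_idx, c(spec_a, spec_b))
    n_shift <- round(cfg$shift_fraction * length(shared))
    shifted <- if (n_shift > 0) sample(shared, n_shift) else integer(0)

    m_g <- runif(ng, cfg$log_mean_range[1], cfg$log_mean_range[2])
    a_g <- numeric(ng)
    a_g[rhy_idx] <- runif(n_rhy, cfg$amplitude_range[1], cfg$amplitude_range[2])
    phase_A <- rep(NA_real_, ng)
    phase_A[rhy_idx] <- rvonmises_hours(n_rhy, cfg$phase_mu_h[1],
                                        cfg$phase_kappa[1])
    phase_B <- phase_A
    phase_B[shifted] <- wrap_hours(phase_A[shifted] + 12)

    a_A <- a_g; a_A[spec_b] <- 0
    a_B <- a_g; a_B[spec_a] <- 0

    times <- seq(0, by = cfg$timestep_h, length.out = cfg$n_timepoints)
    design <- tidyr::expand_grid(
      condition = cfg$conditions,
      time_h = times,
      replicate = seq_len(cfg$n_replicates)
    ) |>
      mutate(zt_h = wrap_hours(.data$time_h),
             sample_id = sprintf("%s_T%02d_R%d", .data$condition,
                                 as.integer(.data$time_h), .data$replicate),
             lib_scaler = runif(dplyr::n(), cfg$library_size_range[1],
                                cfg$library_size_range[2])) |>
      select("sample_id", "condition", "time_h", "zt_h", "replicate",
             "lib_scaler")

    cosA <- outer(phase_A, design$time_h,
                  function(p, t) cos(2 * pi * (t - ifelse(is.na(p), 0, p)) / 24))
    cosB <- outer(phase_B, design$time_h,
                  function(p, t) cos(2 * pi * (t - ifelse(is.na(p), 0, p)) / 24))
    ib <- matrix(rep(design$condition == cfg$conditions[2], each = ng),
                 nrow = ng)
    amp <- ifelse(ib, a_B[row(ib)], a_A[row(ib)])
    cosm <- ifelse(ib, cosB, cosA)
    mu <- exp(m_g[row(ib)] + amp * cosm)
    dimnames(mu) <- list(gene_id, design$sample_id)

    mu_scaled <- sweep(mu, 2, design$lib_scaler, `*`)
    counts <- matrix(rnbinom(length(mu_scaled), mu = mu_scaled,
                             size = 1 / cfg$dispersion),
                     nrow = ng, dimnames = dimnames(mu))

    class_g <- rep("arrhythmic", ng)
    class_g[shared] <- "shared"
    class_g[spec_a] <- "align_specific"
    class_g[spec_b] <- "sc_specific"
    truth <- tibble(
      gene_id = gene_id,
      class = class_g,
      is_rhythmic = seq_len(ng) %in% rhy_idx,
      rhythmic_A = a_A > 0,
      rhythmic_B = a_B > 0,
      phase_A = ifelse(a_A > 0, phase_A, NA_real_),
      phase_B = ifelse(a_B > 0, phase_B, NA_real_),
      amplitude = a_g,
      log_mean = m_g,
      shifted_12h = seq_len(ng) %in% shifted
    )
    list(counts = counts, design = design, truth = truth, mu = mu,
         config = cfg)
  })
}

# von Mises sampler (Best & Fisher 1979), vectorised over batches.
rvonmises_rad <- function(n, mu, kappa) {
  if (kappa == 0) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, n - length(out))
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[ok] - 0.5) * acos(f[ok])
    out <- c(out, th)
  }
  (mu + out[seq_len(n)]) %% (2 * pi)
}

rvonmises_hours <- function(n, mu_h, kappa, period = 24) {
  rad_to_hours(rvonmises_rad(n, hours_to_rad(mu_h, period), kappa), period)
}

#' Draw circular phase samples on the 24-hour clock
#'
#' Samples `n` phases (hours in \[0, 24)) from a von Mises distribution with
#' circular mean `mu_h` and concentration `kappa`; `kappa = 0` gives
#' circular-uniform draws.
#'
#' @param n Number of draws (at least 1).
#' @param mu_h Circular mean, hours.
#' @param kappa Concentration parameter, >= 0.
#' @param seed Integer seed.
#' @return Numeric vector of `n` phases in \[0, 24).
#' @examples
#' simulate_phases(5, mu_h = 18, kappa = 10, seed = 1)
#' @export
simulate_phases <- function(n, mu_h, kappa, seed) {
  if (n < 1) abort("`n` must be at least 1.")
  if (kappa < 0) abort("`kappa` must be non-negative.")
  with_seed(seed, rvonmises_hours(n, mu_h, kappa))
}
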