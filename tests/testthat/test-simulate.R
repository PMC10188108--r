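test_that("track simulation is deterministic and respects its config", {
  cfg <- behavior_sim_config(seed = 11, n_animals = 2, duration_h = 2,
                             dropout_prob = 0, teleport_prob = 0)
  sim1 <- simulate_tracks(cfg)
  sim2 <- simulate_tracks(cfg)
  expect_identical(sim1$tracks, sim2$tracks)
  expect_identical(sim1$truth, sim2$truth)

  # clean-config construction: no dropouts, no jump artifacts
  expect_true(all(sim1$tracks$likelihood >= 0.90))
  for (a in unique(sim1$tracks$animal_id)) {
    tr <- sim1$tracks[sim1$tracks$animal_id == a, ]
    disp <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
    expect_lte(max(disp), 2)
    expect_equal(diff(tr$t), rep(1 / cfg$fps, nrow(tr) - 1))
  }

  # dropouts drawn strictly below the 0.90 likelihood boundary
  cfg_d <- behavior_sim_config(seed = 12, n_animals = 1, duration_h = 1,
                               dropout_prob = 0.2, teleport_prob = 0)
  trd <- simulate_tracks(cfg_d)$tracks
  expect_true(any(trd$likelihood < 0.90))
  expect_true(all(trd$likelihood < 0.90 | trd$likelihood >= 0.95))

  expect_error(behavior_sim_config(seed = 1, duration_h = -1),
               class = "zeitconflict_invalid_config")
  expect_error(behavior_sim_config(seed = 1, fps = 0),
               class = "zeitconflict_invalid_config")
  expect_error(behavior_sim_config(seed = 1, peak_phase_h = 24),
               class = "zeitconflict_invalid_config")
})

test_that("flat-rate tracks produce no detectable daily rhythm", {
  # arrhythmic configuration: pooled hourly activity flat, LSP null
  ps <- vapply(1:15, function(s) {
    cfg <- behavior_sim_config(seed = 100 + s, n_animals = 1,
                               duration_h = 48, rhythmic_fraction = 0,
                               modulation_depth = 0, dropout_prob = 0,
                               teleport_prob = 0)
    tr <- simulate_tracks(cfg)$tracks
    attr(tr, "fps") <- cfg$fps; attr(tr, "zt_offset_h") <- 0
    act <- bin_hourly(detect_movement(tr))
    lsp_permutation_test(tibble::tibble(time_h = act$zt_h,
                                        value = act$norm_distance),
                         n_perm = 99, seed = s)$p_value
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.8)
})

test_that("expression simulation has NB structure with exact mean recovery", {
  cfg <- expression_sim_config(seed = 21, n_genes = 40,
                               rhythmic_fraction = 0.5, dispersion = 0.2)
  sim <- simulate_expression(cfg)
  expect_identical(sim$counts, simulate_expression(cfg)$counts)
  expect_true(all(sim$counts >= 0))
  expect_true(all(sim$counts == round(sim$counts)))
  expect_equal(dim(sim$counts), c(40, 13 * 3 * 2))

  # cosinor refits to the noise-free means recover planted phase/amplitude
  sel <- sim$design$condition == "Aligned"
  for (g in which(sim$truth$rhythmic_A)[1:5]) {
    fit <- cosinor_fit(tibble::tibble(time_h = sim$design$time_h[sel],
                                      value = log(sim$mu[g, sel])))
    dphi <- abs(wrap_signed(fit$acrophase_h - sim$truth$phase_A[g]))
    expect_lt(dphi, 0.1)
    expect_lt(abs(fit$amplitude / sim$truth$amplitude[g] - 1), 0.01)
  }

  expect_error(expression_sim_config(seed = 1, dispersion = 0),
               class = "zeitconflict_invalid_config")
  expect_error(expression_sim_config(seed = 1, n_timepoints = 5,
                                     timestep_h = 4),
               class = "zeitconflict_invalid_config")
})

test_that("zero-amplitude config yields near-zero fitted amplitudes", {
  cfg <- expression_sim_config(seed = 22, n_genes = 30, rhythmic_fraction = 1,
                               amplitude_range = c(0, 0), dispersion = 0.05)
  sim <- simulate_expression(cfg)
  em <- normalize_counts(sim$counts, sim$design, filter = FALSE)
  amps <- gene_cosinor_phases(em, "Aligned")$amplitude
  # pure noise: fitted log2-scale amplitudes stay small relative to the
  # ~0.5 log2 units a 2-fold rhythmic gene would show
  expect_lt(median(amps), 0.2)
})

test_that("a full phase shift moves condition-B fitted phases by 12 h", {
  cfg <- expression_sim_config(seed = 23, n_genes = 30, rhythmic_fraction = 1,
                               shift_fraction = 1, phase_mu_h = 18,
                               phase_kappa = 50, dispersion = 0.05)
  sim <- simulate_expression(cfg)
  selB <- sim$design$condition == "SC"
  phB <- vapply(seq_len(nrow(sim$mu)), function(g) {
    cosinor_fit(tibble::tibble(time_h = sim$design$time_h[selB],
                               value = log(sim$mu[g, selB])))$acrophase_h
  }, numeric(1))
  # planted A phases concentrate at 18, so B phases concentrate at 6
  expect_lt(abs(circular_summary(phB)$mean_h - 6), 0.5)
})

test_that("phase sampling matches its von Mises parameters", {
  p1 <- simulate_phases(5, 18, 10, seed = 3)
  expect_identical(p1, simulate_phases(5, 18, 10, seed = 3))
  expect_true(all(p1 >= 0 & p1 < 24))
  expect_length(simulate_phases(1, 0, 0, seed = 1), 1)

  # concentrated draws: circular mean within 0.3 h of the target
  means <- vapply(1:10, function(s)
    circular_summary(simulate_phases(200, 18, 50, seed = s))$mean_h,
    numeric(1))
  expect_true(all(abs(means - 18) < 0.3))

  # kappa = 0: circular-uniform, Rayleigh mostly non-significant
  ps <- vapply(1:20, function(s)
    rayleigh_test(simulate_phases(1000, 0, 0, seed = s),
                  method = "approximation")$p_value, numeric(1))
  expect_gte(mean(ps > 0.05), 0.8)

  expect_error(simulate_phases(0, 0, 1, seed = 1))
  expect_error(simulate_phases(5, 0, -1, seed = 1))
})
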