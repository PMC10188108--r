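test_that("circular summaries match hand computations", {
  s1 <- circular_summary(c(18, 18, 18))
  expect_equal(s1$mean_h, 18)
  expect_equal(s1$resultant_length, 1)
  expect_equal(s1$circular_variance, 0)

  s2 <- circular_summary(c(0, 6, 12, 18))
  expect_equal(s2$resultant_length, 0, tolerance = 1e-12)
  expect_equal(s2$circular_variance, 1, tolerance = 1e-12)

  s3 <- circular_summary(c(17, 19))
  expect_equal(s3$mean_h, 18, tolerance = 1e-12)
  expect_equal(s3$resultant_length, cos(pi / 12), tolerance = 1e-12)
})

test_that("resultant length is rotation invariant", {
  set.seed(41)
  ph <- runif(50, 0, 24)
  for (k in c(3, 7.5, 13)) {
    expect_equal(circular_summary(ph)$resultant_length,
                 circular_summary((ph + k) %% 24)$resultant_length,
                 tolerance = 1e-12)
  }
})

test_that("Rayleigh test separates concentration from uniformity", {
  r <- rayleigh_test(rep(7, 24), method = "approximation")
  expect_lt(r$p_value, 1e-9)

  even <- seq(0, 23)
  re <- rayleigh_test(even, method = "approximation")
  expect_equal(re$statistic, 0, tolerance = 1e-12)
  expect_gt(re$p_value, 0.99)

  expect_error(rayleigh_test(c(1, 2)), "at least 3")
})

test_that("Rayleigh approximation tracks its Monte-Carlo null at small n", {
  ph <- simulate_phases(10, 6, 1.1, seed = 42)   # moderate concentration
  pa <- rayleigh_test(ph, method = "approximation")$p_value
  pm <- rayleigh_test(ph, method = "monte_carlo", n_mc = 2e4, seed = 1)$p_value
  expect_lt(abs(pa - pm), 0.02)
})

test_that("Watson two-sample test behaves at the boundary and under shifts", {
  ph <- simulate_phases(10, 6, 2, seed = 5)
  same <- watson_two_sample(ph, ph, n_boot = 99, seed = 1)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)

  hits <- vapply(1:10, function(s) {
    a <- simulate_phases(20, 6, 5, seed = s)
    b <- simulate_phases(20, 18, 5, seed = 100 + s)
    watson_two_sample(a, b, n_boot = 999, seed = s)$p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  expect_error(watson_two_sample(1:3, 4:10), "at least 4")
})

test_that("Watson null p-values spread over (0, 1) for same-distribution samples", {
  ps <- vapply(1:30, function(s) {
    a <- simulate_phases(15, 10, 2, seed = s)
    b <- simulate_phases(15, 10, 2, seed = 500 + s)
    watson_two_sample(a, b, n_boot = 99, seed = s)$p_value
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.7)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.001)
})

test_that("phase attribution computes circular distances and verdicts", {
  at <- zeitgeber_phase_attribution(rep(18, 8), offset_h = 12)
  expect_equal(at$distances$d_light, rep(0, 8))
  expect_equal(at$distances$d_temp, rep(12, 8))

  eq <- zeitgeber_phase_attribution(rep(0, 8), offset_h = 12)
  expect_equal(eq$distances$d_light, eq$distances$d_temp)
  expect_equal(eq$verdict, "equidistant")

  hits <- vapply(1:20, function(s) {
    ph <- simulate_phases(15, 18, 10, seed = s)
    zeitgeber_phase_attribution(ph, offset_h = 8)$verdict == "light-closer"
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # distances are symmetric and bounded
  set.seed(6)
  a <- runif(20, 0, 24); b <- runif(20, 0, 24)
  expect_equal(circ_dist_hours(a, b), circ_dist_hours(b, a))
  expect_true(all(circ_dist_hours(a, b) <= 12))

  expect_error(zeitgeber_phase_attribution(numeric(0), 12), "empty")
  expect_error(zeitgeber_phase_attribution(1:5, 5), "even")
})

test_that("half-period alignment merges antiphase animals onto one 24-h rhythm", {
  t <- 0:47
  a <- activity_series(t, 1 + cos(2 * pi * (t - 6) / 24), animal_id = "a")
  b <- activity_series(t, 1 + cos(2 * pi * (t - 18) / 24), animal_id = "b")
  al <- align_half_period(dplyr::bind_rows(a, b), n_perm = 99, seed = 1)
  expect_equal(sum(al$assignments$shifted), 1)
  sp <- lsp_power(tibble::tibble(time_h = al$profile$zt_h,
                                 value = al$profile$mean),
                  period_lo = 10, period_hi = 28)
  expect_equal(attr(sp, "peak_period_h"), 24, tolerance = 0.1)
  p12 <- sp$power[which.min(abs(sp$period_h - 12))]
  expect_lt(p12, attr(sp, "peak_power") / 5)

  # animals already aligned: mean profile unchanged
  al2 <- align_half_period(dplyr::bind_rows(
    a, dplyr::mutate(a, animal_id = "c")), n_perm = 99, seed = 1)
  expect_false(any(al2$assignments$shifted))
  expect_equal(al2$profile$mean, a$norm_distance)
})

test_that("half-period alignment is idempotent and cannot invent 24-h power", {
  t <- 0:47
  set.seed(44)
  series <- purrr::map_dfr(1:6, function(i) {
    ph <- sample(c(6, 18), 1)
    activity_series(t, 1 + cos(2 * pi * (t - ph) / 24) +
                      abs(rnorm(48, 0, 0.05)),
                    animal_id = paste0("a", i))
  })
  al1 <- align_half_period(series, n_perm = 49, seed = 1)
  al2 <- align_half_period(al1$aligned_series, n_perm = 49, seed = 1)
  expect_equal(al2$profile$mean, al1$profile$mean, tolerance = 1e-12)
  expect_false(any(al2$assignments$shifted))

  # pure 12-h waveforms keep their 12-h peak after alignment
  twelve <- purrr::map_dfr(1:6, function(i) {
    activity_series(t, 1 + cos(2 * pi * (t - (i %% 2)) / 12),
                    animal_id = paste0("b", i))
  })
  alt <- align_half_period(twelve, n_perm = 49, seed = 1)
  sp <- lsp_power(tibble::tibble(time_h = alt$profile$zt_h,
                                 value = alt$profile$mean),
                  period_lo = 10, period_hi = 28)
  expect_lt(abs(attr(sp, "peak_period_h") - 12), 0.5)
})
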