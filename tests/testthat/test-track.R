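test_that("pose CSV round trip preserves track content", {
  cfg <- behavior_sim_config(seed = 5, n_animals = 1, duration_h = 0.1)
  tr <- simulate_tracks(cfg)$tracks
  path <- withr::local_tempfile(fileext = ".csv")
  write_pose_csv(tr, path)
  rd <- read_pose_csv(path, fps = 2, animal_id = "a")
  expect_equal(nrow(rd), nrow(tr))
  expect_equal(rd$t[2] - rd$t[1], 0.5)
  expect_equal(rd$x, tr$x, tolerance = 1e-12)
  expect_equal(rd$likelihood, tr$likelihood, tolerance = 1e-12)
})

test_that("pose CSV parsing flags malformed headers and empty cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("scorer,s,s,s", "bodyparts,c,c,c", "coords,x,y,likelihood",
               "0,1.0,2.0,0.99", "1,,2.1,0.98", "2,1.2,2.2,0.97"), path)
  tr <- read_pose_csv(path)
  expect_equal(tr$likelihood[2], 0)

  writeLines(c("scorer,s,s", "bodyparts,c,c", "coords,x,y",
               "0,1.0,2.0"), path)
  expect_error(read_pose_csv(path), "likelihood")

  writeLines(c("wrong,s,s,s", "bodyparts,c,c,c", "coords,x,y,likelihood",
               "0,1,2,0.9"), path)
  expect_error(read_pose_csv(path), "row 1")
})

test_that("clean_track interpolates low-likelihood and jump frames", {
  tr <- tibble::tibble(animal_id = "a", t = (0:2) / 2,
                       x = c(0, 9, 1), y = c(0, 9, 0),
                       likelihood = c(1, 0.85, 1))
  cl <- clean_track(tr)
  expect_equal(cl$x[2], 0.5)
  expect_equal(cl$y[2], 0)
  expect_true(cl$interpolated[2])

  # clean input is untouched
  ok <- tibble::tibble(animal_id = "a", t = (0:9) / 2,
                       x = seq(0, 0.9, by = 0.1), y = 0, likelihood = 1)
  expect_equal(clean_track(ok)$x, ok$x)

  # a single 3-cm outlier is removed; cleaned displacements all <= 2 cm
  x <- rep(0, 10); x[5] <- 3
  tr2 <- tibble::tibble(animal_id = "a", t = (0:9) / 2, x = x, y = 0,
                        likelihood = 1)
  cl2 <- clean_track(tr2)
  expect_true(all(abs(diff(cl2$x)) <= 2))
  expect_true(all(abs(diff(cl2$y)) <= 2))

  expect_error(clean_track(tibble::tibble(animal_id = "a", t = 0:1,
                                          x = 0:1, y = 0,
                                          likelihood = c(0.1, 0.2))))
})

test_that("clean_track is idempotent on artifact-laden tracks", {
  for (s in 1:5) {
    set.seed(s)
    n <- 200
    tr <- tibble::tibble(animal_id = "a", t = (seq_len(n) - 1) / 2,
                         x = cumsum(rnorm(n, 0, 0.3)),
                         y = cumsum(rnorm(n, 0, 0.3)),
                         likelihood = ifelse(runif(n) < 0.1,
                                             runif(n, 0, 0.89),
                                             runif(n, 0.95, 1)))
    c1 <- clean_track(tr)
    c2 <- clean_track(c1)
    expect_equal(c2$x, c1$x, tolerance = 1e-12)
    expect_equal(c2$y, c1$y, tolerance = 1e-12)
  }
})

test_that("movement detection applies the speed and duration rules", {
  # exactly 6 frames at threshold speed at 2 fps: one bout
  sp <- c(0, rep(0.03, 6), rep(0, 5))
  dm <- detect_movement(track_from_speeds(sp))
  expect_equal(sum(dm$moving), 6)
  expect_equal(nrow(bout_table(dm)), 1)

  # 5 supra-threshold frames: too short, no bout
  sp2 <- c(0, rep(0.05, 5), rep(0, 6))
  dm2 <- detect_movement(track_from_speeds(sp2))
  expect_false(any(dm2$moving))
  expect_equal(nrow(bout_table(dm2)), 0)

  # immobile: no bouts
  dm3 <- detect_movement(track_from_speeds(rep(0, 20)))
  expect_false(any(dm3$moving))
})

test_that("movement detection matches the brute-force run oracle", {
  for (s in 1:200) {
    set.seed(s)
    n <- sample(20:80, 1)
    sp <- c(0, round(abs(rnorm(n - 1, 0.03, 0.02)), 3))
    dm <- detect_movement(track_from_speeds(sp))
    expect_identical(dm$moving, oracle_moving_mask(dm$speed, fps = 2))
  }
})

test_that("hourly binning normalises, handles inactivity, and conserves distance", {
  # one frame per half-hour over 3 h; distances chosen per hour
  fps <- 2
  n <- 3 * 3600 * fps
  sp <- rep(0, n)
  # bouts: hour 1 covers 2 cm, hour 2: 4 cm, hour 3: 8 cm (speeds above threshold)
  hour_idx <- floor(((seq_len(n)) - 1) / (3600 * fps))
  sp[hour_idx == 0][2:101] <- 2 / 100 * fps
  sp[hour_idx == 1][2:101] <- 4 / 100 * fps
  sp[hour_idx == 2][2:101] <- 8 / 100 * fps
  dm <- detect_movement(track_from_speeds(sp), v_min = 0.01)
  act <- bin_hourly(dm)
  expect_equal(act$distance_cm, c(2, 4, 8), tolerance = 1e-9)
  expect_equal(act$norm_distance, c(0.25, 0.5, 1))
  # conservation: per-hour sums equal total masked displacement
  expect_equal(sum(act$distance_cm), sum(dm$speed[dm$moving]) / fps)

  # fully inactive animal: all-zero normalised series, flagged
  dm0 <- detect_movement(track_from_speeds(rep(0, 7200)))
  act0 <- bin_hourly(dm0)
  expect_equal(act0$norm_distance, rep(0, nrow(act0)))
  expect_true(attr(act0, "inactive"))

  # an hour fully inside a bout scores 100% active
  sp_full <- c(0, rep(0.05, 7199))
  actf <- bin_hourly(detect_movement(track_from_speeds(sp_full)))
  expect_equal(actf$pct_active[1], 100, tolerance = 0.1)
})

test_that("group profiles average, smooth, and validate grids", {
  a <- activity_series(0:47, rep(c(2, 4), 24), animal_id = "a")
  b <- dplyr::mutate(a, animal_id = "b")
  prof <- group_mean_profile(dplyr::bind_rows(a, b))
  expect_equal(prof$mean, a$norm_distance)
  expect_equal(prof$sem, rep(0, 48))
  expect_equal(prof$n_animals, rep(2L, 48))

  # antiphase cosines of equal amplitude: constant mean
  t <- 0:47
  ca <- activity_series(t, 1 + cos(2 * pi * t / 24), animal_id = "a")
  cb <- activity_series(t, 1 - cos(2 * pi * t / 24), animal_id = "b")
  pm <- group_mean_profile(dplyr::bind_rows(ca, cb))
  expect_lt(diff(range(pm$mean)), 1e-9)

  # smoothing shrinks white-noise variance
  set.seed(7)
  noisy <- purrr::map_dfr(1:6, function(i)
    activity_series(0:47, abs(rnorm(48)) + 0.1,
                    animal_id = paste0("n", i)))
  pn <- group_mean_profile(noisy)
  expect_lt(var(pn$smoothed), var(pn$mean))

  bad <- dplyr::mutate(b, zt_h = zt_h + 1)
  expect_error(group_mean_profile(dplyr::bind_rows(a, bad)), "grid")
})
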