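#' Clean a pose track by likelihood and jump filtering
#'
#' Frames with tracking likelihood below `likelihood_min` are removed and
#' linearly interpolated (x and y separately) between the nearest surviving
#' frames; leading/trailing removed frames take the nearest surviving value.
#' Frames whose displacement from the previous frame then still exceeds
#' `max_jump_cm` are removed and interpolated the same way, with one re-check
#' pass (no iteration to a fixpoint). The output has the same length as the
#' input; interpolated frames are flagged in an `interpolated` column.
#'
#' @param track Track tibble (`t`, `x`, `y`, `likelihood`; single animal).
#' @param likelihood_min Minimum acceptable likelihood (default 0.90).
#' @param max_jump_cm Maximum plausible per-frame displacement (default 2 cm).
#' @return The cleaned track, same rows, with `interpolated` added.
#' @examples
#' tr <- tibble::tibble(animal_id = "a", t = 0:2 / 2,
#'                      x = c(0, 5, 1), y = 0, likelihood = c(1, 0.5, 1))
#' clean_track(tr)
#' @export
clean_track <- function(track, likelihood_min = 0.90, max_jump_cm = 2.0) {
  stopifnot(all(c("x", "y", "likelihood") %in% names(track)))
  n <- nrow(track)
  x <- track$x; y <- track$y
  bad <- track$likelihood < likelihood_min | is.na(x) | is.na(y)
  if (all(bad)) abort("all frames fail the likelihood filter; nothing to interpolate from.")
  interp <- function(v, bad) {
    if (!any(bad)) return(v)
    good <- which(!bad)
    approx(good, v[good], xout = seq_len(n), rule = 2)$y
  }
  x <- interp(x, bad); y <- interp(y, bad)
  flagged <- bad
  # jump rule after the likelihood rule, then re-checked once
  for (pass in 1:2) {
    disp <- c(0, sqrt(diff(x)^2 + diff(y)^2))
    jump <- disp > max_jump_cm
    if (!any(jump)) break
    if (all(jump | flagged)) abort("all frames fail cleaning; nothing to interpolate from.")
    x <- interp(x, jump); y <- interp(y, jump)
    flagged <- flagged | jump
  }
  out <- track
  out$x <- x; out$y <- y
  out$interpolated <- flagged
  out
}

# Per-frame speed (cm/s): displacement from the previous frame times fps;
# the first frame has speed 0.
frame_speed <- function(x, y, fps) {
  c(0, sqrt(diff(x)^2 + diff(y)^2)) * fps
}

#' Detect movement bouts in a cleaned track
#'
#' An animal counts as moving when its frame speed is at least `v_min` for an
#' uninterrupted run of at least `min_dur_s` seconds (6 frames at 2 fps); any
#' shorter run of supra-threshold speed is treated as tracking noise. Returns
#' the track with a logical `moving` column (true only inside bouts) and a
#' `speed` column.
#'
#' @param track Cleaned track tibble for one animal.
#' @param v_min Speed threshold, cm/s (default 0.03).
#' @param min_dur_s Minimum bout duration, seconds (default 3).
#' @param fps Frames per second; taken from the track attribute if absent.
#' @return The track with `speed` and `moving` columns; attribute `fps` kept.
#' @seealso [bout_table()] for the bout list.
#' @export
detect_movement <- function(track, v_min = 0.03, min_dur_s = 3.0, fps = NULL) {
  fps <- fps %||% attr(track, "fps") %||% (1 / diff(track$t[1:2]))
  speed <- frame_speed(track$x, track$y, fps)
  # tolerance absorbs float noise from reconstructing positions; 1e-9 cm/s
  # is far below any physical speed resolution
  fast <- speed >= v_min - 1e-9
  min_frames <- ceiling(min_dur_s * fps)
  r <- rle(fast)
  keep <- r$values & r$lengths >= min_frames
  moving <- inverse.rle(list(values = keep, lengths = r$lengths))
  out <- track
  out$speed <- speed
  out$moving <- moving
  attr(out, "fps") <- fps
  attr(out, "zt_offset_h") <- attr(track, "zt_offset_h") %||% 0
  out
}

#' Summarise movement bouts
#'
#' @param track A track processed by [detect_movement()].
#' @return Tibble with one row per bout: start/end frame, start time (s),
#'   duration (s) and distance covered (cm).
#' @export
bout_table <- function(track) {
  stopifnot("moving" %in% names(track))
  fps <- attr(track, "fps") %||% (1 / diff(track$t[1:2]))
  r <- rle(track$moving)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  idx <- which(r$values)
  purrr::map_dfr(idx, function(i) {
    fr <- starts[i]:ends[i]
    tibble(start_frame = starts[i], end_frame = ends[i],
           start_t = track$t[starts[i]],
           duration_s = r$lengths[i] / fps,
           distance_cm = sum(track$speed[fr]) / fps)
  })
}

#' Bin a track into hourly activity on the ZT clock
#'
#' Sums within-bout distance into wall-clock hourly bins (a partial first hour
#' is binned to its clock hour), computes the percent of frames spent moving,
#' and normalises each animal's hourly distance to its maximum hour. A fully
#' inactive animal (all distances zero) gets an all-zero `norm_distance` and
#' is flagged via the `inactive` attribute so group profiles can exclude it.
#'
#' @param track A track processed by [detect_movement()].
#' @param zt_offset_h ZT hour at recording start; defaults to the track attribute.
#' @return An activity-series tibble: `animal_id`, `zt_h` (integer hour since
#'   ZT0 of day 1, not folded), `distance_cm`, `pct_active`, `norm_distance`.
#' @export
bin_hourly <- function(track, zt_offset_h = NULL) {
  stopifnot("moving" %in% names(track))
  if (nrow(track) == 0) abort("empty track.")
  fps <- attr(track, "fps") %||% (1 / diff(track$t[1:2]))
  zt0 <- zt_offset_h %||% attr(track, "zt_offset_h") %||% 0
  hour <- floor(track$t / 3600 + zt0)
  disp <- track$speed / fps
  df <- tibble(
    animal_id = track$animal_id[1],
    hour = hour,
    d = ifelse(track$moving, disp, 0),
    m = track$moving
  ) |>
    group_by(.data$animal_id, zt_h = .data$hour) |>
    summarise(distance_cm = sum(.data$d),
              pct_active = 100 * mean(.data$m), .groups = "drop")
  mx <- max(df$distance_cm)
  df$norm_distance <- if (mx > 0) df$distance_cm / mx else rep(0, nrow(df))
  attr(df, "inactive") <- mx == 0
  df
}

#' Group mean activity profile with SEM and smoothing
#'
#' Averages the normalised hourly activity of a set of animals on a common ZT
#' grid, attaches the standard error of the mean, and smooths the mean with a
#' centered moving average over `smooth_h` hourly bins (an even window of
#' width 4 covers bins t-2 ... t+1). Animals flagged fully inactive are
#' excluded from the average.
#'
#' @param series Stacked activity series (rows from [bin_hourly()]) with
#'   columns `animal_id`, `zt_h`, `norm_distance`.
#' @param smooth_h Smoothing window in hours (default 4).
#' @param group Label stored on the result.
#' @return A `group_profile` tibble: `zt_h`, `mean`, `sem`, `n_animals`,
#'   `smoothed`.
#' @export
group_mean_profile <- function(series, smooth_h = 4, group = "group") {
  stopifnot(all(c("animal_id", "zt_h", "norm_distance") %in% names(series)))
  active <- series |>
    group_by(.data$animal_id) |>
    filter(max(.data$norm_distance) > 0) |>
    ungroup()
  if (nrow(active) == 0) abort("no active animals to average.")
  grids <- split(active$zt_h, active$animal_id)
  ref <- sort(unique(grids[[1]]))
  same <- vapply(grids, function(g) identical(sort(unique(g)), ref), logical(1))
  if (!all(same)) abort("animals are not on a common ZT grid.")
  prof <- active |>
    group_by(.data$zt_h) |>
    summarise(mean = mean(.data$norm_distance),
              sem = if (dplyr::n() > 1) sd(.data$norm_distance) / sqrt(dplyr::n()) else 0,
              n_animals = dplyr::n(), .groups = "drop") |>
    arrange(.data$zt_h)
  prof$smoothed <- moving_average_centered(prof$mean, smooth_h)
  attr(prof, "group") <- group
  attr(prof, "smooth_h") <- smooth_h
  attr(prof, "smooth_alignment") <- "bins t-2 ... t+1 for width 4"
  class(prof) <- c("group_profile", class(prof))
  prof
}
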