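#' @importFrom ggplot2 ggplot aes geom_line geom_ribbon geom_raster geom_col
#'   geom_hline geom_point labs scale_fill_viridis_c coord_polar theme_minimal
#'   autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot a group mean activity profile
#'
#' Mean normalised activity with an SEM ribbon and the smoothed profile.
#'
#' @param object A `group_profile` from [group_mean_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot group_profile
#' @export
autoplot.group_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$zt_h)) +
    geom_ribbon(aes(ymin = .data$mean - .data$sem,
                    ymax = .data$mean + .data$sem), alpha = 0.25) +
    geom_line(aes(y = .data$mean), colour = "grey40") +
    geom_line(aes(y = .data$smoothed), linewidth = 1) +
    labs(x = "ZT (h)", y = "normalised activity",
         title = attr(object, "group")) +
    theme_minimal()
}

#' Plot a Lomb-Scargle periodogram
#'
#' @param object An `lsp_spectrum` from [lsp_power()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lsp_spectrum
#' @export
autoplot.lsp_spectrum <- function(object, ...) {
  ggplot(object, aes(.data$period_h, .data$power)) +
    geom_line() +
    geom_point(data = object[which.max(object$power), ], colour = "red") +
    labs(x = "period (h)", y = "normalised LSP power") +
    theme_minimal()
}

#' Plot a Morlet wavelet power spectrum
#'
#' @param object A `wavelet_spectrum`.
#' @param ... Unused.
#' @return A ggplot (time x period heat map of power).
#' @method autoplot wavelet_spectrum
#' @export
autoplot.wavelet_spectrum <- function(object, ...) {
  df <- tidyr::expand_grid(time_h = object$times,
                           period_h = object$periods)
  df$power <- as.vector(object$power)  # period varies fastest, matching columns
  ggplot(df, aes(.data$time_h, .data$period_h, fill = .data$power)) +
    geom_raster() +
    scale_fill_viridis_c() +
    labs(x = "time (h)", y = "period (h)", title = object$label) +
    theme_minimal()
}

#' Plot enrichment score tracks
#'
#' One line per term over the 24-h clock with the enrichment threshold.
#'
#' @param object An `enrichment_track`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot enrichment_track
#' @export
autoplot.enrichment_track <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  ggplot(object, aes(.data$zt_h, .data$score, colour = .data$term_id)) +
    geom_line() +
    geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    labs(x = "ZT (h)", y = "mean -log10 adjusted p", colour = "term") +
    theme_minimal()
}

#' Rose plot of a circular phase sample
#'
#' @param phases Phases in hours.
#' @param binwidth_h Bin width in hours.
#' @return A ggplot in polar coordinates.
#' @export
plot_phase_rose <- function(phases, binwidth_h = 1) {
  df <- tibble(bin = floor(wrap_hours(phases) / binwidth_h) * binwidth_h) |>
    dplyr::count(.data$bin)
  ggplot(df, aes(.data$bin, .data$n)) +
    geom_col(width = binwidth_h) +
    coord_polar(start = 0) +
    ggplot2::scale_x_continuous(limits = c(0, 24),
                                breaks = seq(0, 23, by = 6)) +
    labs(x = "phase (ZT h)", y = "count") +
    theme_minimal()
}
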