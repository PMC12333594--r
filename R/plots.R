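#' Plot a conditioning profile against its null envelope
#'
#' @param profile Conditioning profile (e.g. [cohort_conditioning_shift()]).
#' @param envelope A [null_envelope()] on the same time axis.
#' @return A ggplot object: profile line over the shaded pointwise CI.
#' @export
plot_conditioning <- function(profile, envelope) {
  d <- tidy.null_envelope(envelope)
  d$value <- as.numeric(profile)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_ms)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), colour = "grey50",
                       linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$value), colour = "firebrick") +
    ggplot2::labs(x = "time (ms)", y = "conditioning phase shift (rad)",
                  title = "Conditioning interhemispheric phase shift vs null")
}

#' @describeIn condition_erps Grand-average waveforms for selected channels.
#' @param object An `erp_result`.
#' @param channels Channels to draw (default: up to 6 posterior/midline).
#' @param ... Unused.
#' @export
autoplot.erp_result <- function(object, channels = NULL, ...) {
  d <- object$grand
  if (is.null(channels)) {
    pref <- c("Fz", "P7", "P8", "O1", "O2", "CP1")
    channels <- intersect(pref, unique(d$channel))
    if (!length(channels)) channels <- utils::head(unique(d$channel), 6)
  }
  d <- d[d$channel %in% channels, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_ms, y = .data$amplitude_uV,
                                  colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(x = "time (ms)", y = "amplitude (µV)")
}

#' Plot per-condition spectral centroids by electrode
#'
#' @param table A [cohort_centroids()] tibble.
#' @param conditions Which conditions to draw.
#' @return A ggplot object showing subject points and condition means.
#' @export
plot_centroids <- function(table, conditions = c("trust", "untrust")) {
  d <- table[table$condition %in% conditions, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$electrode, y = .data$centroid_hz,
                                  colour = .data$condition)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4),
                        alpha = 0.4) +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 3,
                          position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::stat_summary(fun = mean, geom = "line",
                          ggplot2::aes(group = .data$condition),
                          position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(y = "spectral centroid (Hz)")
}
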