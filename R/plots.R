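# Diagnostic ggplot2 figures. Depth axes are reversed so that the pial
# surface (0 um) sits at the top, matching how laminar data are shown.

#' Plot a depth-time profile
#'
#' Heat map of a trial-averaged LFP or CSD profile; for CSD, blue marks
#' sinks (negative) and warm colours sources.
#'
#' @param object A [depth_time_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.depth_time_profile <- function(object, ...) {
  df <- tidy(object)
  lab <- if (object$units == "uA_per_mm3") "CSD (uA/mm^3)" else "LFP (mV)"
  lim <- max(abs(df$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s * 1000,
                                   y = .data$depth_um,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-lim, lim)) +
    ggplot2::labs(x = "time (ms)", y = "depth (um)", fill = lab) +
    ggplot2::theme_minimal()
}

#' Plot a depth-resolved PSD
#' @param object A `depth_psd`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.depth_psd <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_hz, y = .data$depth_um,
                                   fill = .data$power_dbmv)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "frequency (Hz)", y = "depth (um)",
                  fill = "PSD (dBmV)") +
    ggplot2::theme_minimal()
}

#' Plot a spectrogram
#' @param object A `spectrogram`.
#' @param ... Unused.
#' @return A ggplot (dB scale).
#' @export
autoplot.spectrogram <- function(object, ...) {
  df <- tidy(object)
  df$power_db <- 10 * log10(pmax(df$power_mv2_hz, 1e-12))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$freq_hz,
                                   fill = .data$power_db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)",
                  fill = "power (dBmV)") +
    ggplot2::theme_minimal()
}

#' Plot a PETH
#' @param object A `peth` tibble (from [compute_peth()]) or the layer-wise
#'   output of [population_peth_by_layer()].
#' @param ... Unused.
#' @return A ggplot of baseline-subtracted rate vs time.
#' @export
autoplot.peth <- function(object, ...) {
  df <- as_tibble(object)
  df$t_ms <- (df$bin_start_s + df$bin_end_s) / 2 * 1000
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t_ms, y = .data$rate_hz)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "time from stimulus (ms)",
                  y = "rate - baseline (spikes/s)") +
    ggplot2::theme_minimal()
  if ("layer" %in% names(df)) p <- p + ggplot2::facet_wrap(~layer, ncol = 1)
  p
}

#' Plot stimulus-induced PSD change
#' @param object A `psd_change`.
#' @param depth_range_um Optional depth range to average over before
#'   plotting.
#' @param ... Unused.
#' @return A ggplot of percent change vs frequency.
#' @export
autoplot.psd_change <- function(object, depth_range_um = NULL, ...) {
  rows <- seq_along(object$depth_um)
  if (!is.null(depth_range_um)) {
    rows <- which(object$depth_um >= depth_range_um[1] &
                  object$depth_um <= depth_range_um[2])
  }
  df <- tibble(freq_hz = object$freq_hz,
               percent = colMeans(object$percent[rows, , drop = FALSE],
                                  na.rm = TRUE))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_hz, y = .data$percent)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "frequency (Hz)", y = "PSD change (%)") +
    ggplot2::theme_minimal()
}
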