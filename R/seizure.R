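# Epileptiform event detection: z-scored low-frequency band power with a
# duration rule. Episodes of abnormally strong 0.5-10 Hz activity sustained
# for at least 10 s are detected on the LFP at ~500 um cortical depth.

#' z-scored band-power trace
#'
#' Steps: (1) STFT spectrogram of the signal (2-s Hamming window, 0.1-s
#' step); (2) per frequency bin, subtract that bin's median over all window
#' centres (in linear power units); (3) average the median-subtracted power
#' over the 0.5-10 Hz bins; (4) z-score the resulting trace with its own
#' session mean and SD.
#'
#' @param signal LFP at the target depth (mV).
#' @param fs_hz Sampling rate (Hz).
#' @param band_hz Band, default `c(0.5, 10)`.
#' @param window_s,step_s STFT parameters (defaults 2 s / 0.1 s).
#' @param min_session_s Minimum session length for a stable baseline
#'   (default 60 s).
#' @return A tibble with `time_s` (window centres) and `z`.
#' @export
band_zscore_trace <- function(signal, fs_hz, band_hz = c(0.5, 10),
                              window_s = 2.0, step_s = 0.1,
                              min_session_s = 60) {
  if (length(signal) / fs_hz < min_session_s) {
    abort(sprintf("session must be at least %g s for z-scoring.", min_session_s))
  }
  spec <- stft_spectrogram(signal, fs_hz, window_s, step_s,
                           freq_range_hz = band_hz)
  meds <- apply(spec$power, 2L, median)
  centred <- sweep(spec$power, 2L, meds, `-`)
  trace <- rowMeans(centred)
  s <- sd(trace)
  if (!is.finite(s) || s == 0) abort("degenerate trace: band power has zero variance.")
  tibble(time_s = spec$time_s, z = (trace - mean(trace)) / s,
         step_s = spec$step_s)
}

#' Detect threshold-run events in a z trace
#'
#' Finds maximal runs of consecutive window centres with `z > z_threshold`.
#' A run of `m` consecutive centres spans `(m - 1) * step + step = m * step`
#' seconds (span between first and last centre plus one step); runs with
#' span >= `min_duration_s` become events with `start`/`end` at the first/
#' last centre -/+ half a step. Runs separated by even a single
#' sub-threshold step are kept separate.
#'
#' @param z_trace Tibble from [band_zscore_trace()] (`time_s`, `z`).
#' @param step_s Step between window centres (taken from the trace if
#'   present).
#' @param z_threshold Threshold in SD units (default 2).
#' @param min_duration_s Minimum sustained duration (default 10 s).
#' @return A tibble of events: `start_s`, `end_s`, `duration_s`, `peak_z`.
#' @export
detect_events <- function(z_trace, step_s = NULL, z_threshold = 2.0,
                          min_duration_s = 10.0) {
  step_s <- step_s %||% z_trace$step_s[1]
  above <- z_trace$z > z_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in which(r$values)) {
    m <- r$lengths[k]
    span <- m * step_s
    if (span >= min_duration_s - 1e-9) {
      i0 <- starts[k]; i1 <- ends[k]
      out[[length(out) + 1L]] <- tibble(
        start_s = z_trace$time_s[i0] - step_s / 2,
        end_s = z_trace$time_s[i1] + step_s / 2,
        peak_z = max(z_trace$z[i0:i1])
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble(start_s = numeric(0), end_s = numeric(0),
                  duration_s = numeric(0), peak_z = numeric(0)))
  }
  ev <- dplyr::bind_rows(out)
  ev$duration_s <- ev$end_s - ev$start_s
  ev[, c("start_s", "end_s", "duration_s", "peak_z")]
}

#' Detect epileptiform events in a laminar session
#'
#' Applies [band_zscore_trace()] then [detect_events()] to the LFP row
#' nearest the target cortical depth (500 um by default; the nearest row
#' must lie within 50 um).
#'
#' @param lfp A per-depth-row [laminar_lfp()].
#' @param target_depth_um Cortical depth to analyse (default 500).
#' @param band_hz,window_s,step_s,z_threshold,min_duration_s Detector
#'   parameters (defaults: 0.5-10 Hz, 2 s, 0.1 s, 2 SD, 10 s).
#' @return Event tibble as from [detect_events()], with a `depth_um_used`
#'   column.
#' @export
detect_session_events <- function(lfp, target_depth_um = 500,
                                  band_hz = c(0.5, 10), window_s = 2.0,
                                  step_s = 0.1, z_threshold = 2.0,
                                  min_duration_s = 10.0) {
  i <- nearest_depth_row(lfp$depth_um, target_depth_um, max_dist_um = 50)
  z <- band_zscore_trace(lfp$values[i, ], lfp$sampling_rate_hz, band_hz,
                         window_s, step_s)
  # session-relative clock: trace times already include start_time_s via
  # stft_spectrogram(start_time_s = 0); shift to the LFP's clock
  z$time_s <- z$time_s + lfp$start_time_s
  ev <- detect_events(z, z_threshold = z_threshold,
                      min_duration_s = min_duration_s)
  ev$depth_um_used <- rep(lfp$depth_um[i], nrow(ev))
  ev
}
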