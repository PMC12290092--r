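# Short-time Fourier analysis. One estimator serves every spectral consumer
# in the package: Hamming-tapered one-sided periodograms on a sliding window
# (2 s window, 0.1 s step by default, i.e. Welch with 95% overlap),
# normalised as power spectral density in mV^2/Hz. A band-limited direct-DFT
# path computes exactly the same bins as the FFT path and is used
# automatically when only a narrow band is requested (the epileptiform
# detector needs 0.5-10 Hz only).

# Periodic Hamming window (DFT-even), standard for spectral estimation.
hamming_periodic <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / n)

# Hamming-periodogram PSD at the given window start indices (1-based) and
# frequency-bin indices (1-based, bin k -> frequency (k-1)*fs/L).
# Returns an n_windows x n_bins matrix in signal-units^2 / Hz.
stft_power_at <- function(signal, fs_hz, starts, win_len, bin_idx,
                          chunk_cols = 512L) {
  w <- hamming_periodic(win_len)
  scale <- 1 / (fs_hz * sum(w^2))
  nf_full <- floor(win_len / 2) + 1L
  one_sided <- rep(2, length(bin_idx))
  one_sided[bin_idx == 1L] <- 1
  if (win_len %% 2L == 0L) one_sided[bin_idx == nf_full] <- 1

  nb <- length(bin_idx)
  use_direct <- nb <= min(600L, max(64L, win_len %/% 4L))
  if (use_direct) {
    ang <- 2 * pi * outer(bin_idx - 1L, 0:(win_len - 1L)) / win_len
    Cmat <- cos(ang); Smat <- sin(ang)   # nb x L
  }
  out <- matrix(0, length(starts), nb)
  for (ofs in seq(1L, length(starts), by = chunk_cols)) {
    cols <- ofs:min(ofs + chunk_cols - 1L, length(starts))
    seg <- matrix(signal[outer(0:(win_len - 1L), starts[cols], `+`)],
                  nrow = win_len) * w
    if (use_direct) {
      out[cols, ] <- t((Cmat %*% seg)^2 + (Smat %*% seg)^2)
    } else {
      # pack pairs of real segments into complex FFTs
      m <- length(cols)
      pw <- matrix(0, win_len, m)
      for (p in seq(1L, m, by = 2L)) {
        if (p + 1L <= m) {
          Z <- fft(seg[, p] + 1i * seg[, p + 1L])
          Zr <- Conj(Z[c(1L, win_len:2L)])
          pw[, p] <- Mod((Z + Zr) / 2)^2
          pw[, p + 1L] <- Mod((Z - Zr) / (2i))^2
        } else {
          pw[, p] <- Mod(fft(seg[, p]))^2
        }
      }
      out[cols, ] <- t(pw[bin_idx, , drop = FALSE])
    }
  }
  sweep(out * scale, 2L, one_sided, `*`)
}

#' Short-time Fourier spectrogram
#'
#' Sliding-window spectrogram with a periodic Hamming taper, normalised as a
#' one-sided power spectral density: white noise of variance \eqn{s^2} has
#' mean PSD \eqn{s^2/(fs/2)} per Hz, and summing power over frequency times
#' the bin width recovers the signal variance (Parseval). Frequency
#' resolution is `1/window_s` (0.5 Hz at the default 2-s window).
#'
#' @param signal Numeric vector (mV).
#' @param fs_hz Sampling rate (Hz).
#' @param window_s Window length in seconds (default 2).
#' @param step_s Step between window starts in seconds (default 0.1).
#' @param freq_range_hz Optional `c(lo, hi)`: restrict the returned bins to
#'   this band (the computation is then band-limited too).
#' @param start_time_s Session time of the first sample.
#' @return An object of class `spectrogram`: list with `time_s` (window
#'   centres), `freq_hz`, and `power` (time x freq, mV^2/Hz).
#' @export
stft_spectrogram <- function(signal, fs_hz, window_s = 2.0, step_s = 0.1,
                             freq_range_hz = NULL, start_time_s = 0) {
  stopifnot_scalar_number(fs_hz, "fs_hz", positive = TRUE)
  win_len <- round(window_s * fs_hz)
  step_len <- max(1L, round(step_s * fs_hz))
  if (length(signal) < win_len) abort("signal shorter than one window.")
  if (step_s > window_s) warn("step exceeds window length; gaps between windows.")
  starts <- seq(1L, length(signal) - win_len + 1L, by = step_len)
  freq <- (seq_len(floor(win_len / 2) + 1L) - 1L) * fs_hz / win_len
  bin_idx <- seq_along(freq)
  if (!is.null(freq_range_hz)) {
    bin_idx <- which(freq >= freq_range_hz[1] - 1e-9 &
                     freq <= freq_range_hz[2] + 1e-9)
    if (length(bin_idx) == 0L) abort("freq_range_hz selects no bins.")
  }
  power <- stft_power_at(signal, fs_hz, starts, win_len, bin_idx)
  structure(
    list(time_s = start_time_s + (starts - 1L + (win_len - 1) / 2) / fs_hz,
         freq_hz = freq[bin_idx], power = power,
         window_s = win_len / fs_hz, step_s = step_len / fs_hz),
    class = "spectrogram"
  )
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d windows x %d bins, %g-%g Hz, window %g s step %g s\n",
              nrow(x$power), ncol(x$power), min(x$freq_hz), max(x$freq_hz),
              x$window_s, x$step_s))
  invisible(x)
}

#' Tidy a spectrogram
#' @param x A `spectrogram`.
#' @param ... Unused.
#' @return Long tibble with `time_s`, `freq_hz`, `power_mv2_hz`.
#' @export
tidy.spectrogram <- function(x, ...) {
  tibble(
    time_s = rep(x$time_s, times = length(x$freq_hz)),
    freq_hz = rep(x$freq_hz, each = length(x$time_s)),
    power_mv2_hz = as.vector(x$power)
  )
}

#' Depth-resolved power spectral density in dB re 1 mV^2/Hz
#'
#' Per depth row, the mean over non-excluded spectrogram window centres of
#' the Hamming-periodogram PSD, converted to decibels relative to
#' 1 mV^2/Hz ("dBmV"): `10 * log10(PSD / 1 mV^2/Hz)`.
#'
#' @param lfp A per-depth-row [laminar_lfp()].
#' @param exclude Optional [exclusion_mask_from_events()] mask; windows
#'   whose centres fall in an excluded interval are dropped.
#' @param window_s,step_s STFT parameters (defaults 2 s, 0.1 s).
#' @param freq_range_hz Optional band restriction.
#' @param min_duration_s Minimum post-exclusion data span (default 10 s).
#' @return Object of class `depth_psd`: `depth_um`, `freq_hz`,
#'   `power_dbmv` (depth x freq).
#' @export
depth_psd <- function(lfp, exclude = NULL, window_s = 2.0, step_s = 0.1,
                      freq_range_hz = NULL, min_duration_s = 10) {
  if (!inherits(lfp, "laminar_lfp")) abort("`lfp` must be a laminar_lfp.")
  fs <- lfp$sampling_rate_hz
  win_len <- round(window_s * fs)
  step_len <- max(1L, round(step_s * fs))
  n <- ncol(lfp$values)
  if (n < win_len) abort("recording shorter than one STFT window.")
  starts <- seq(1L, n - win_len + 1L, by = step_len)
  centers <- lfp$start_time_s + (starts - 1L + (win_len - 1) / 2) / fs
  keep <- rep(TRUE, length(starts))
  if (!is.null(exclude) && nrow(exclude) > 0) {
    keep <- !points_in_intervals(centers, exclude$start_s, exclude$end_s)
  }
  if (!any(keep)) abort("all data excluded; no windows remain.")
  if (sum(keep) * step_len / fs < min_duration_s) {
    abort(sprintf("post-exclusion duration < %g s.", min_duration_s))
  }
  freq <- (seq_len(floor(win_len / 2) + 1L) - 1L) * fs / win_len
  bin_idx <- seq_along(freq)
  if (!is.null(freq_range_hz)) {
    bin_idx <- which(freq >= freq_range_hz[1] - 1e-9 &
                     freq <= freq_range_hz[2] + 1e-9)
  }
  pd <- matrix(0, nrow(lfp$values), length(bin_idx))
  for (r in seq_len(nrow(lfp$values))) {
    pw <- stft_power_at(lfp$values[r, ], fs, starts[keep], win_len, bin_idx)
    pd[r, ] <- colMeans(pw)
  }
  zero <- pd == 0
  if (any(zero)) warn(sprintf("%d PSD cells have exactly zero power (-Inf dB).",
                              sum(zero)))
  structure(
    list(depth_um = lfp$depth_um, freq_hz = freq[bin_idx],
         power_dbmv = 10 * log10(pd), n_windows = sum(keep)),
    class = "depth_psd"
  )
}

#' Tidy a depth PSD
#' @param x A `depth_psd`.
#' @param ... Unused.
#' @return Long tibble `depth_um`, `freq_hz`, `power_dbmv`.
#' @export
tidy.depth_psd <- function(x, ...) {
  tibble(
    depth_um = rep(x$depth_um, times = length(x$freq_hz)),
    freq_hz = rep(x$freq_hz, each = length(x$depth_um)),
    power_dbmv = as.vector(x$power_dbmv)
  )
}

# Inclusive frequency-bin selection with edges snapped to the nearest bins.
snap_band_bins <- function(freq_hz, band_hz) {
  lo <- freq_hz[which.min(abs(freq_hz - band_hz[1]))]
  hi <- freq_hz[which.min(abs(freq_hz - band_hz[2]))]
  which(freq_hz >= lo - 1e-9 & freq_hz <= hi + 1e-9)
}

#' Session-level band power scalar
#'
#' Reduces a depth PSD to one number: the mean over the frequency bins of a
#' band (edges snapped to the nearest bins, inclusive) and over the depth
#' rows in a range. By default the mean is taken of the dB values; set
#' `mode = "db_of_mean"` to average in linear power first and convert once.
#'
#' @param psd A `depth_psd`.
#' @param band_hz Frequency band, default `c(30, 120)` (gamma).
#' @param depth_range_um Optional `c(lo, hi)` depth range; default all rows.
#' @param mode `"mean_db"` (default) or `"db_of_mean"`.
#' @return Scalar dBmV.
#' @export
band_power <- function(psd, band_hz = c(30, 120), depth_range_um = NULL,
                       mode = c("mean_db", "db_of_mean")) {
  mode <- match.arg(mode)
  bins <- snap_band_bins(psd$freq_hz, band_hz)
  if (length(bins) == 0L) abort("band contains no frequency bins.")
  rows <- seq_along(psd$depth_um)
  if (!is.null(depth_range_um)) {
    rows <- which(psd$depth_um >= depth_range_um[1] &
                  psd$depth_um <= depth_range_um[2])
    if (length(rows) == 0L) abort("depth range contains no rows.")
  }
  vals <- psd$power_dbmv[rows, bins, drop = FALSE]
  if (mode == "mean_db") mean(vals) else 10 * log10(mean(10^(vals / 10)))
}

#' Stimulus-induced PSD change relative to baseline
#'
#' For each depth row and frequency bin, the percent change
#' `100 * (P_stim - P_base) / P_base`, where `P_stim` and `P_base` are
#' trial-averaged mean PSDs over spectrogram windows whose centres fall in
#' the stimulus and baseline windows (relative to trial onset). Bins with
#' zero baseline power are set to `NA` and excluded from summaries.
#'
#' @param lfp A per-depth-row [laminar_lfp()].
#' @param trials A [trial_table()] (pass only the trials to analyse, e.g.
#'   visual trials surviving exclusion).
#' @param stim_window_s Window relative to onset containing the stimulus,
#'   e.g. `c(0, 5)` for a 5-s grating.
#' @param base_window_s Baseline window relative to onset, default
#'   `c(-2, -1)`.
#' @param window_s,step_s STFT parameters.
#' @param freq_range_hz Optional band restriction.
#' @return Object of class `psd_change`: `depth_um`, `freq_hz`,
#'   `percent` (depth x freq, NA where baseline is zero), `n_trials`.
#' @export
stimulus_psd_change <- function(lfp, trials, stim_window_s = c(0, 5),
                                base_window_s = c(-2, -1), window_s = 2.0,
                                step_s = 0.1, freq_range_hz = NULL) {
  if (nrow(trials) == 0L) abort("no trials to analyse.")
  fs <- lfp$sampling_rate_hz
  win_len <- round(window_s * fs)
  step_len <- max(1L, round(step_s * fs))
  n <- ncol(lfp$values)
  starts <- seq(1L, n - win_len + 1L, by = step_len)
  centers <- lfp$start_time_s + (starts - 1L + (win_len - 1) / 2) / fs
  freq <- (seq_len(floor(win_len / 2) + 1L) - 1L) * fs / win_len
  bin_idx <- seq_along(freq)
  if (!is.null(freq_range_hz)) {
    bin_idx <- which(freq >= freq_range_hz[1] - 1e-9 &
                     freq <= freq_range_hz[2] + 1e-9)
  }
  stim_of_trial <- vector("list", nrow(trials))
  base_of_trial <- vector("list", nrow(trials))
  for (t in seq_len(nrow(trials))) {
    on <- trials$onset_s[t]
    stim_of_trial[[t]] <- which(centers >= on + stim_window_s[1] &
                                centers <= on + stim_window_s[2])
    base_of_trial[[t]] <- which(centers >= on + base_window_s[1] &
                                centers <= on + base_window_s[2])
  }
  ok <- lengths(stim_of_trial) > 0 & lengths(base_of_trial) > 0
  if (!any(ok)) abort("no trial has spectrogram windows in both windows.")
  needed <- sort(unique(c(unlist(stim_of_trial[ok]), unlist(base_of_trial[ok]))))
  remap <- integer(length(starts)); remap[needed] <- seq_along(needed)

  nd <- nrow(lfp$values)
  p_stim <- matrix(0, nd, length(bin_idx))
  p_base <- matrix(0, nd, length(bin_idx))
  for (r in seq_len(nd)) {
    pw <- stft_power_at(lfp$values[r, ], fs, starts[needed], win_len, bin_idx)
    s_acc <- matrix(0, sum(ok), length(bin_idx))
    b_acc <- matrix(0, sum(ok), length(bin_idx))
    kk <- 0L
    for (t in which(ok)) {
      kk <- kk + 1L
      s_acc[kk, ] <- colMeans(pw[remap[stim_of_trial[[t]]], , drop = FALSE])
      b_acc[kk, ] <- colMeans(pw[remap[base_of_trial[[t]]], , drop = FALSE])
    }
    p_stim[r, ] <- colMeans(s_acc)
    p_base[r, ] <- colMeans(b_acc)
  }
  percent <- 100 * (p_stim - p_base) / p_base
  percent[p_base == 0] <- NA_real_
  structure(
    list(depth_um = lfp$depth_um, freq_hz = freq[bin_idx], percent = percent,
         n_trials = sum(ok)),
    class = "psd_change"
  )
}

#' Tidy a stimulus PSD change
#' @param x A `psd_change`.
#' @param ... Unused.
#' @return Long tibble `depth_um`, `freq_hz`, `percent_change`.
#' @export
tidy.psd_change <- function(x, ...) {
  tibble(
    depth_um = rep(x$depth_um, times = length(x$freq_hz)),
    freq_hz = rep(x$freq_hz, each = length(x$depth_um)),
    percent_change = as.vector(x$percent)
  )
}

#' Band summary of a stimulus PSD change
#'
#' Mean percent change over a frequency band (edges snapped to bins,
#' inclusive) and optional depth range, skipping flagged (NA) bins.
#'
#' @param change A `psd_change`.
#' @param band_hz Band, default gamma `c(30, 120)`.
#' @param depth_range_um Optional depth range.
#' @return Scalar percent change.
#' @export
psd_change_summary <- function(change, band_hz = c(30, 120),
                               depth_range_um = NULL) {
  bins <- snap_band_bins(change$freq_hz, band_hz)
  rows <- seq_along(change$depth_um)
  if (!is.null(depth_range_um)) {
    rows <- which(change$depth_um >= depth_range_um[1] &
                  change$depth_um <= depth_range_um[2])
  }
  mean(change$percent[rows, bins], na.rm = TRUE)
}
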