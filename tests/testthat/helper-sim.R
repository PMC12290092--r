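# Shared builders for small simulated fixtures. Problem sizes here are
# deliberately reduced (lower sampling rate, fewer rows/trials) so the suite
# stays fast; the signal model and all analysis parameters keep their
# reference defaults unless a test says otherwise.

# Small laminar session: 1 kHz, 16 rows at 40 um (span 600 um).
quick_cfg <- function(seed, ...) {
  defaults <- list(
    seed = seed, n_depth_rows = 16, depth_spacing_um = 40,
    sampling_rate_hz = 1000,
    evoked = list(list(depth_center_um = 350, depth_sd_um = 70,
                       peak_amplitude_uA_mm3 = -5, latency_s = 0.025,
                       temporal_sd_s = 0.008, source_offset_um = 150)),
    gamma = list(amplitude_mv = 0.03, depth_band_um = c(100, 600)),
    trials = list(n_tactile = 8, n_visual = 6),
    spikes = list(n_clusters = 6, baseline_rate_hz = 5, evoked_rate_hz = 15,
                  evoked_window_s = c(0, 0.05),
                  cluster_depths_um = seq(100, 600, length.out = 6))
  )
  dots <- list(...)
  defaults[names(dots)] <- dots   # plain replacement (no recursive merge)
  do.call(sim_config, defaults)
}

# Medium cohort session used by the end-to-end recovery checks:
# 1 kHz, 32 rows at 30 um (span 930 um), 30 tactile + 10 visual trials.
cohort_cfg <- function(seed = 1) {
  sim_config(
    seed = seed, n_depth_rows = 32, depth_spacing_um = 30,
    sampling_rate_hz = 1000,
    evoked = list(list(depth_center_um = 400, depth_sd_um = 100,
                       peak_amplitude_uA_mm3 = -5, latency_s = 0.025,
                       temporal_sd_s = 0.008, source_offset_um = 200)),
    gamma = list(amplitude_mv = 0.03, depth_band_um = c(100, 600)),
    trials = list(n_tactile = 30, n_visual = 10),
    spikes = list(n_clusters = 10, baseline_rate_hz = 5, evoked_rate_hz = 15,
                  evoked_window_s = c(0, 0.05),
                  cluster_depths_um = seq(100, 900, length.out = 10))
  )
}

cohort_params <- function(...) {
  pipeline_params(psd_freq_range_hz = c(0.5, 150),
                  psd_depth_range_um = c(100, 600),
                  stft_step_s = 0.25,
                  stim_window_s = c(1, 4), base_window_s = c(-1.9, -1.1),
                  write_csd_profile = FALSE, ...)
}

# Interval Jaccard index.
jaccard <- function(a1, a2, b1, b2) {
  inter <- max(0, min(a2, b2) - max(a1, b1))
  inter / (max(a2, b2) - min(a1, b1))
}

# Apply the pipeline's CSD measurement operator (forward model -> spline
# iCSD -> depth smoothing -> peak extraction) to a session's noiseless
# ground-truth CSD; the expected value of the measured peak under no noise.
operator_truth_peak <- function(session, params = cohort_params(),
                                fs = session$lfp$sampling_rate_hz) {
  tf <- session$truth$true_csd_fine
  elec <- session$lfp$depth_um
  phi <- forward_lfp_from_csd(tf, elec, params$sigma_S_per_m,
                              params$disk_radius_um)
  tt <- seq(params$csd_window_s[1], params$csd_window_s[2], by = 1 / fs)
  vals <- matrix(0, length(elec), length(tt))
  idx <- which(tt >= -1e-12 & tt <= max(phi$time_s) + 1e-12)
  vals[, idx] <- phi$values[, seq_along(idx)]
  prof <- depth_time_profile(elec, tt, vals, units = "mV")
  est <- smooth_csd_depth(estimate_csd(prof,
                                       csd_config(params$sigma_S_per_m,
                                                  params$disk_radius_um)),
                          params$smooth_sd_mm)
  suppressMessages(extract_peak_response(est, params$csd_peak_depth_um,
                                         params$csd_peak_window_s))
}

# Predicted gamma-band mean percent PSD change for a sinusoidal burst of
# amplitude a (mV) against the simulator's pink background: injected
# one-sided power a^2/2 lands near the burst frequency, so the mean over
# the N band bins of 100 * dP/P_base is approximately
# (100 / N) * (a^2 / 2) / (df * P_pink(f_burst)).
predicted_gamma_change <- function(a, rms_mv, fs, band = c(30, 120),
                                   f_burst = 70, df = 0.5) {
  n_bins <- length(seq(band[1], band[2], by = df))
  100 / n_bins * (a^2 / 2) / (df * pink_noise_psd(f_burst, rms_mv, fs))
}
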