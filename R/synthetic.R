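# Synthetic laminar sessions with known ground truth. The simulator builds
# an LFP as: forward-modelled evoked CSD responses locked to tactile stimuli
# + spatially correlated pink (1/f) background noise + 70-Hz gamma bursts
# during visual stimulation + low-frequency (1-4 Hz) high-amplitude
# epileptiform episodes with cosine-ramped onsets, plus inhomogeneous
# Poisson spike trains. Every stage of the analysis pipeline has a recovery
# oracle against the returned ground truth.

#' Simulation configuration
#'
#' Defaults mirror the reference recording protocol: 2.5 kHz LFP sampling,
#' 20-um depth rows, 50 tactile trials (two 20-ms air puffs, 500 ms apart)
#' and 50 visual trials (5-s gratings) in randomised order with 3-5 s
#' inter-trial intervals, a granular-layer current sink near 400 um with a
#' paired return source, 70-Hz gamma during visual stimulation, and optional
#' 1-4 Hz epileptiform episodes.
#'
#' @param seed Mandatory RNG seed.
#' @param duration_s Session length in seconds, or `NULL` to fit the trial
#'   schedule plus margins.
#' @param n_depth_rows,depth_spacing_um Probe depth grid (default 64 rows at
#'   20 um).
#' @param sampling_rate_hz LFP rate (default 2500).
#' @param noise List: `rms_mv` (pink-noise RMS per row, default 0.05),
#'   `spatial_corr_um` (exponential correlation length, default 200).
#' @param evoked List of sink components, each a list with
#'   `depth_center_um`, `depth_sd_um`, `peak_amplitude_uA_mm3` (negative =
#'   sink), `latency_s`, `temporal_sd_s`, `source_offset_um`.
#' @param gamma List: `frequency_hz` (70), `amplitude_mv`, `depth_band_um`,
#'   `visual_only` (TRUE), `ramp_s`.
#' @param epileptiform Data frame (or NULL) with `start_s`, `duration_s`,
#'   `frequency_hz` in 1-4 Hz, `amplitude_mult` (multiple of the background
#'   0.5-10 Hz band RMS).
#' @param trials List: `n_tactile`, `n_visual`, `iti_range_s` (c(3, 5)),
#'   `tactile_isi_s` (0.5), `visual_duration_s` (5), `first_onset_s` (8).
#' @param spikes List: `n_clusters`, `baseline_rate_hz`, `evoked_rate_hz`,
#'   `evoked_window_s`, `cluster_depths_um` (NULL = spread 100-900 um).
#' @param sigma_S_per_m,disk_radius_um Forward-model constants (0.3 S/m,
#'   500 um).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       duration_s = NULL,
                       n_depth_rows = 64, depth_spacing_um = 20,
                       sampling_rate_hz = 2500,
                       noise = list(),
                       evoked = NULL,
                       gamma = list(),
                       epileptiform = NULL,
                       trials = list(),
                       spikes = list(),
                       sigma_S_per_m = 0.3, disk_radius_um = 500) {
  if (missing(seed)) abort("`seed` is mandatory in sim_config().")
  noise <- modifyList(list(rms_mv = 0.05, spatial_corr_um = 200), noise)
  gamma <- modifyList(list(frequency_hz = 70, amplitude_mv = 0.03,
                           depth_band_um = c(100, 600), visual_only = TRUE,
                           ramp_s = 0.1), gamma)
  trials <- modifyList(list(n_tactile = 50, n_visual = 50,
                            iti_range_s = c(3, 5), tactile_isi_s = 0.5,
                            visual_duration_s = 5, first_onset_s = 8), trials)
  spikes <- modifyList(list(n_clusters = 10, baseline_rate_hz = 5,
                            evoked_rate_hz = 15, evoked_window_s = c(0, 0.05),
                            cluster_depths_um = NULL), spikes)
  if (is.null(evoked)) {
    evoked <- list(list(depth_center_um = 400, depth_sd_um = 100,
                        peak_amplitude_uA_mm3 = -5, latency_s = 0.025,
                        temporal_sd_s = 0.008, source_offset_um = 300))
  }
  if (spikes$baseline_rate_hz < 0 || spikes$evoked_rate_hz < 0) {
    abort("spike rates must be nonnegative.")
  }
  span <- (n_depth_rows - 1) * depth_spacing_um
  if (gamma$depth_band_um[1] > span) {
    abort("gamma depth band lies outside the probe span.")
  }
  if (!is.null(epileptiform) && nrow(epileptiform) > 0) {
    if (any(epileptiform$frequency_hz < 1 | epileptiform$frequency_hz > 4)) {
      abort("epileptiform frequencies must lie in [1, 4] Hz.")
    }
    if (!is.null(duration_s) &&
        any(epileptiform$start_s + epileptiform$duration_s > duration_s)) {
      abort("epileptiform episodes must lie within the session duration.")
    }
  }
  cfg <- list(seed = as.integer(seed), duration_s = duration_s,
              n_depth_rows = as.integer(n_depth_rows),
              depth_spacing_um = depth_spacing_um,
              sampling_rate_hz = sampling_rate_hz, noise = noise,
              evoked = evoked, gamma = gamma, epileptiform = epileptiform,
              trials = trials, spikes = spikes,
              sigma_S_per_m = sigma_S_per_m, disk_radius_um = disk_radius_um)
  structure(cfg, class = "sim_config")
}

#' Depth-row grid of a simulation configuration
#' @param cfg A [sim_config()].
#' @return Depths in micrometres, one per row, starting at 0 (pia).
#' @export
sim_depth_grid <- function(cfg) (seq_len(cfg$n_depth_rows) - 1L) * cfg$depth_spacing_um

#' Ground-truth evoked CSD profile
#'
#' Builds the evoked CSD as a sum of separable Gaussian(depth) x
#' Gaussian(time) sink components, each paired with an opposite-sign return
#' source at `source_offset_um`. The source amplitude is scaled so that the
#' discrete depth integral of the profile is exactly zero at every time
#' (charge balance), compensating the small mass lost where a Gaussian is
#' truncated at the probe ends.
#'
#' @param cfg A [sim_config()].
#' @param depth_step_um Grid spacing of the truth profile (default 1 um, 20x
#'   finer than the electrode spacing, so forward-model quadrature error is
#'   negligible).
#' @param time_step_s Time step (default `1/sampling_rate_hz`).
#' @return A [depth_time_profile()] in uA/mm^3 on the fine grid; time runs
#'   from 0 (stimulus onset) past the slowest component.
#' @export
make_evoked_csd_truth <- function(cfg, depth_step_um = 1,
                                  time_step_s = NULL) {
  if (length(cfg$evoked) == 0L) abort("no evoked components configured.")
  time_step_s <- time_step_s %||% (1 / cfg$sampling_rate_hz)
  span <- (cfg$n_depth_rows - 1L) * cfg$depth_spacing_um
  z <- seq(0, span, by = depth_step_um)
  t_end <- max(vapply(cfg$evoked, function(e) e$latency_s + 5 * e$temporal_sd_s,
                      numeric(1)))
  tt <- seq(0, t_end, by = time_step_s)
  vals <- matrix(0, length(z), length(tt))
  for (e in cfg$evoked) {
    if (e$depth_center_um + 3 * e$depth_sd_um > span ||
        e$depth_center_um - 3 * e$depth_sd_um < 0) {
      warn("evoked component extends beyond the probe span by > 3 depth SDs.")
    }
    sink_z <- exp(-0.5 * ((z - e$depth_center_um) / e$depth_sd_um)^2)
    src_z <- exp(-0.5 * ((z - e$depth_center_um - e$source_offset_um) /
                           e$depth_sd_um)^2)
    # balance: scale the source so the discrete depth integral cancels
    if (sum(src_z) > 0) src_z <- src_z * (sum(sink_z) / sum(src_z))
    g_t <- exp(-0.5 * ((tt - e$latency_s) / e$temporal_sd_s)^2)
    vals <- vals + e$peak_amplitude_uA_mm3 * outer(sink_z - src_z, g_t)
  }
  depth_time_profile(z, tt, vals, units = "uA_per_mm3")
}

#' Forward-model LFP from a CSD profile (quadrature oracle)
#'
#' Computes the potential each depth row would record from a CSD profile by
#' direct trapezoidal quadrature of the disc kernel
#' \eqn{\phi(z_i) = (1/2\sigma) \int C(z) [\sqrt{(z-z_i)^2+R^2} - |z-z_i|] dz}
#' over the profile's own (fine, uniform) depth grid. This is independent of
#' the spline machinery in [estimate_csd()] and serves as its oracle.
#'
#' @param csd A [depth_time_profile()] in uA/mm^3 on a uniform depth grid.
#' @param out_depth_um Electrode depths at which to evaluate the potential.
#' @param sigma_S_per_m Conductivity (default 0.3 S/m).
#' @param disk_radius_um Disc radius R (default 500 um).
#' @return A [depth_time_profile()] in mV at `out_depth_um`, same time grid.
#' @export
forward_lfp_from_csd <- function(csd, out_depth_um,
                                 sigma_S_per_m = 0.3, disk_radius_um = 500) {
  if (!inherits(csd, "depth_time_profile") || csd$units != "uA_per_mm3") {
    abort("`csd` must be a depth_time_profile in uA/mm^3.")
  }
  if (!is_uniform_grid(csd$depth_um, tol = 1e-6)) {
    abort("CSD depth grid must be uniform.")
  }
  stopifnot_scalar_number(sigma_S_per_m, "sigma_S_per_m", positive = TRUE)
  stopifnot_scalar_number(disk_radius_um, "disk_radius_um", positive = TRUE)
  z_src <- csd$depth_um / 1000
  z_out <- out_depth_um / 1000
  dz <- diff(z_src)[1]
  wts <- rep(dz, length(z_src)); wts[c(1, length(wts))] <- dz / 2
  K <- csd_disk_kernel(z_out, z_src, disk_radius_um / 1000)
  phi <- (K %*% (wts * csd$values)) / (2 * sigma_S_per_m)
  depth_time_profile(out_depth_um, csd$time_s, phi, units = "mV")
}

# --- internal generators ---------------------------------------------------

# Pink (1/f) noise via FFT shaping: power flat below `knee_hz`, 1/f above,
# with an 8th-order rolloff above `lp_hz` mimicking the acquisition
# low-pass. Normalised so the series has the requested RMS in expectation.
pink_shape <- function(f, knee_hz = 0.5, lp_hz = 100) {
  (1 / pmax(f, knee_hz)) / (1 + (f / lp_hz)^4)^2
}

pink_noise_matrix <- function(n_rows, n_samp, fs, rms_mv, depths_um,
                              corr_um) {
  nf <- floor(n_samp / 2)
  f <- (1:nf) * fs / n_samp
  amp <- sqrt(pink_shape(f))
  # normalise expected variance to rms^2 (each retained bin pair carries
  # 4 * amp^2 of the total sum of squares)
  amp <- amp * rms_mv / sqrt(4 * sum(amp^2) / n_samp)
  base <- matrix(0, n_rows, n_samp)
  for (r in seq_len(n_rows)) {
    re <- rnorm(nf); im <- rnorm(nf)
    spec <- complex(real = re, imaginary = im) * amp
    full <- complex(length.out = n_samp)
    full[2:(nf + 1)] <- spec
    full[n_samp:(n_samp - nf + 2)] <- Conj(spec[seq_len(nf - 1)])
    if (n_samp %% 2 == 0) full[nf + 1] <- complex(real = sqrt(2) * re[nf] * amp[nf])
    base[r, ] <- Re(fft(full, inverse = TRUE)) / sqrt(n_samp)
  }
  if (n_rows > 1 && corr_um > 0) {
    Sig <- exp(-abs(outer(depths_um, depths_um, `-`)) / corr_um)
    base <- t(chol(Sig)) %*% base
  }
  base
}

#' Theoretical PSD of the simulator's background noise
#'
#' One-sided PSD (mV^2/Hz) of the pink background at the simulated RMS;
#' used by recovery tests to predict stimulus-induced power changes
#' analytically.
#'
#' @param f Frequencies (Hz).
#' @param rms_mv Configured noise RMS.
#' @param fs Sampling rate.
#' @return PSD values at `f`.
#' @export
pink_noise_psd <- function(f, rms_mv, fs) {
  shape <- pink_shape(f)
  # normalisation: integral of the one-sided PSD over (0, fs/2] = rms^2
  norm <- stats::integrate(function(x) pink_shape(x), 1e-3, fs / 2,
                           subdivisions = 2000L, rel.tol = 1e-8)$value
  rms_mv^2 * shape / norm
}

# Cosine-ramped envelope: 1 inside, raised-cosine ramps of `ramp_s` at the
# ends of [0, dur].
ramped_envelope <- function(t_rel, dur, ramp_s) {
  env <- as.numeric(t_rel >= 0 & t_rel <= dur)
  if (ramp_s > 0) {
    up <- t_rel >= 0 & t_rel < ramp_s
    env[up] <- 0.5 * (1 - cos(pi * t_rel[up] / ramp_s))
    dn <- t_rel > dur - ramp_s & t_rel <= dur
    env[dn] <- 0.5 * (1 - cos(pi * (dur - t_rel[dn]) / ramp_s))
  }
  env
}

# RMS of the band-limited (FFT mask) component of a series.
band_rms <- function(x, fs, band) {
  n <- length(x)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  X <- fft(x)
  X[!(f >= band[1] & f <= band[2])] <- 0
  sqrt(mean(Re(fft(X, inverse = TRUE) / n)^2))
}

draw_trial_schedule <- function(cfg) {
  tr <- cfg$trials
  modality <- sample(c(rep("tactile", tr$n_tactile), rep("visual", tr$n_visual)))
  n <- length(modality)
  dur <- ifelse(modality == "tactile", tr$tactile_isi_s + 0.02,
                tr$visual_duration_s)
  iti <- runif(n, tr$iti_range_s[1], tr$iti_range_s[2])
  onset <- tr$first_onset_s + c(0, cumsum(dur[-n] + iti[-n]))
  tibble(
    trial_id = seq_len(n), modality = modality, onset_s = onset,
    n_stimuli = ifelse(modality == "tactile", 2L, 1L),
    stim_param = ifelse(modality == "tactile",
                        sprintf("air_puff isi=%gs", tr$tactile_isi_s),
                        sprintf("grating dur=%gs", tr$visual_duration_s)),
    dur_s = dur
  )
}

#' Simulate a laminar session
#'
#' Generates a full session (geometry, LFP, trials, spikes) plus ground
#' truth, fully reproducible from `cfg$seed`. See [sim_config()] for the
#' signal model.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_session` with `geometry`, `lfp`, `trials`,
#'   `spikes`, and `truth` (list: `true_csd` on the electrode grid,
#'   `true_csd_fine`, `event_intervals`, `gamma_amplitude_mv`,
#'   `evoked`, `spike_rates`, `seed`).
#' @export
simulate_session <- function(cfg) {
  if (!inherits(cfg, "sim_config")) abort("`cfg` must be a sim_config.")
  with_seed(cfg$seed, {
    fs <- cfg$sampling_rate_hz
    depths <- sim_depth_grid(cfg)

    sched <- draw_trial_schedule(cfg)
    needed <- max(sched$onset_s + sched$dur_s) + 5
    duration <- cfg$duration_s %||% ceiling(needed)
    if (max(sched$onset_s + sched$dur_s) + 1 > duration) {
      abort("trials do not fit in duration_s at the drawn inter-trial intervals.")
    }
    n_samp <- round(duration * fs)
    t_axis <- (seq_len(n_samp) - 1L) / fs

    lfp_vals <- pink_noise_matrix(cfg$n_depth_rows, n_samp, fs,
                                  cfg$noise$rms_mv, depths,
                                  cfg$noise$spatial_corr_um)

    # evoked CSD -> forward LFP template, added at every tactile air puff
    truth_fine <- NULL; true_csd_elec <- NULL
    if (length(cfg$evoked) > 0) {
      truth_fine <- make_evoked_csd_truth(cfg)
      template <- forward_lfp_from_csd(truth_fine, depths,
                                       cfg$sigma_S_per_m, cfg$disk_radius_um)
      n_tpl <- length(template$time_s)
      puffs <- with(cfg$trials, {
        on <- sched$onset_s[sched$modality == "tactile"]
        c(on, on + tactile_isi_s)
      })
      for (p in puffs) {
        i0 <- round(p * fs) + 1L
        idx <- i0:(i0 + n_tpl - 1L)
        ok <- idx <= n_samp
        lfp_vals[, idx[ok]] <- lfp_vals[, idx[ok]] + template$values[, ok]
      }
      true_csd_elec <- depth_time_profile(
        depths, truth_fine$time_s,
        apply(truth_fine$values, 2, function(col)
          approx(truth_fine$depth_um, col, xout = depths)$y),
        units = "uA_per_mm3")
    }

    # gamma bursts during visual stimulation
    g <- cfg$gamma
    gamma_rows <- which(depths >= g$depth_band_um[1] &
                        depths <= g$depth_band_um[2])
    if (g$amplitude_mv > 0 && length(gamma_rows) > 0) {
      vis <- sched[sched$modality == "visual", ]
      for (t in seq_len(nrow(vis))) {
        i0 <- round(vis$onset_s[t] * fs) + 1L
        i1 <- min(round((vis$onset_s[t] + vis$dur_s[t]) * fs), n_samp)
        idx <- i0:i1
        tt <- t_axis[idx] - vis$onset_s[t]
        burst <- g$amplitude_mv *
          sin(2 * pi * g$frequency_hz * tt + runif(1, 0, 2 * pi)) *
          ramped_envelope(tt, vis$dur_s[t], g$ramp_s)
        lfp_vals[gamma_rows, idx] <-
          lfp_vals[gamma_rows, idx] + rep(burst, each = length(gamma_rows))
      }
    }

    # epileptiform episodes: sinusoid at mult x background 0.5-10 Hz RMS
    ep <- cfg$epileptiform
    event_intervals <- tibble(start_s = numeric(0), end_s = numeric(0))
    if (!is.null(ep) && nrow(ep) > 0) {
      det_row <- nearest_depth_row(depths, min(500, max(depths)), quiet = TRUE)
      bg_rms <- band_rms(lfp_vals[det_row, ], fs, c(0.5, 10))
      for (k in seq_len(nrow(ep))) {
        if (ep$start_s[k] + ep$duration_s[k] > duration) {
          abort("epileptiform episode extends past the session end.")
        }
        i0 <- round(ep$start_s[k] * fs) + 1L
        i1 <- min(round((ep$start_s[k] + ep$duration_s[k]) * fs), n_samp)
        idx <- i0:i1
        tt <- t_axis[idx] - ep$start_s[k]
        osc <- ep$amplitude_mult[k] * bg_rms * sqrt(2) *
          sin(2 * pi * ep$frequency_hz[k] * tt + runif(1, 0, 2 * pi)) *
          ramped_envelope(tt, ep$duration_s[k], 1.0)
        lfp_vals[, idx] <- lfp_vals[, idx] + rep(osc, each = cfg$n_depth_rows)
      }
      event_intervals <- merge_intervals(ep$start_s, ep$start_s + ep$duration_s)
    }

    # spikes: inhomogeneous Poisson, baseline + boxcar evoked on tactile
    sp <- cfg$spikes
    cl_depths <- sp$cluster_depths_um %||%
      seq(100, min(900, max(depths)), length.out = sp$n_clusters)
    tact_on <- sched$onset_s[sched$modality == "tactile"]
    spike_rows <- vector("list", sp$n_clusters)
    for (cl in seq_len(sp$n_clusters)) {
      n_base <- rpois(1, sp$baseline_rate_hz * duration)
      times <- runif(n_base, 0, duration)
      wlen <- diff(sp$evoked_window_s)
      if (sp$evoked_rate_hz > 0 && wlen > 0) {
        for (on in tact_on) {
          n_ev <- rpois(1, sp$evoked_rate_hz * wlen)
          times <- c(times, on + runif(n_ev, sp$evoked_window_s[1],
                                       sp$evoked_window_s[2]))
        }
      }
      spike_rows[[cl]] <- tibble(cluster_id = cl, spike_time_s = sort(times),
                                 cluster_depth_um = cl_depths[cl])
    }
    spikes <- dplyr::bind_rows(spike_rows)
    spikes <- spike_table(spikes$cluster_id, spikes$spike_time_s,
                          spikes$cluster_depth_um)

    geometry <- channel_geometry(seq_len(cfg$n_depth_rows), depths)
    lfp <- laminar_lfp(lfp_vals, fs, depths, start_time_s = 0)
    trials <- trial_table(sched$trial_id, sched$modality, sched$onset_s,
                          sched$n_stimuli, sched$stim_param)
    structure(
      list(geometry = geometry, lfp = lfp, trials = trials, spikes = spikes,
           truth = list(true_csd = true_csd_elec, true_csd_fine = truth_fine,
                        event_intervals = event_intervals,
                        gamma_amplitude_mv = g$amplitude_mv,
                        evoked = cfg$evoked,
                        spike_rates = sp, seed = cfg$seed)),
      class = "sim_session")
  })
}

#' Simulate a two-group cohort
#'
#' Generates `n_per_group` control-like sessions from `base_cfg` and the
#' same number of contrast ("KO-like") sessions differing only by the stated
#' deltas: a multiplicative scaling of the evoked CSD amplitude, an additive
#' latency shift, and a scaling of the gamma burst amplitude. Per-session
#' seeds derive deterministically from `seed`.
#'
#' @param base_cfg A [sim_config()] (its own seed is ignored).
#' @param group_deltas List with any of `evoked_amplitude_scale`,
#'   `latency_shift_s`, `gamma_amplitude_scale` (defaults 1, 0, 1).
#' @param n_per_group Sessions per group (>= 1).
#' @param seed Master seed.
#' @return A tibble with columns `group` ("control"/"ko"), `session_id`,
#'   `seed`, and a list-column `session` of `sim_session` objects.
#' @export
simulate_cohort <- function(base_cfg, group_deltas = list(), n_per_group = 8,
                            seed = 1) {
  if (n_per_group < 1) abort("n_per_group must be >= 1.")
  d <- modifyList(list(evoked_amplitude_scale = 1, latency_shift_s = 0,
                       gamma_amplitude_scale = 1), group_deltas)
  apply_deltas <- function(cfg) {
    cfg$evoked <- lapply(cfg$evoked, function(e) {
      e$peak_amplitude_uA_mm3 <- e$peak_amplitude_uA_mm3 * d$evoked_amplitude_scale
      e$latency_s <- e$latency_s + d$latency_shift_s
      e
    })
    cfg$gamma$amplitude_mv <- cfg$gamma$amplitude_mv * d$gamma_amplitude_scale
    cfg
  }
  rows <- list()
  for (grp in c("control", "ko")) {
    for (i in seq_len(n_per_group)) {
      s <- derive_seed(seed, i + ifelse(grp == "ko", 1000L, 0L))
      cfg_i <- base_cfg
      cfg_i$seed <- s
      if (grp == "ko") cfg_i <- apply_deltas(cfg_i)
      class(cfg_i) <- "sim_config"
      rows[[length(rows) + 1L]] <- tibble(
        group = grp, session_id = sprintf("%s_%02d", grp, i), seed = s,
        session = list(simulate_session(cfg_i)))
    }
  }
  dplyr::bind_rows(rows)
}
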