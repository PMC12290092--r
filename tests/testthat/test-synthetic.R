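test_that("ground-truth CSD is charge-balanced with the sink where configured", {
  # sink and source well separated so the pair minimum is the sink centre
  cfg <- quick_cfg(1, evoked = list(list(
    depth_center_um = 200, depth_sd_um = 50, peak_amplitude_uA_mm3 = -5,
    latency_s = 0.025, temporal_sd_s = 0.008, source_offset_um = 250)))
  truth <- make_evoked_csd_truth(cfg)
  peak <- max(abs(truth$values))
  # depth integral vanishes at every time sample
  expect_lt(max(abs(colSums(truth$values))), 1e-9 * peak)
  # sink minimum sits at the configured (depth, latency) grid point
  ij <- which(truth$values == min(truth$values), arr.ind = TRUE)[1, ]
  expect_equal(truth$depth_um[ij[1]], 200)
  expect_equal(truth$time_s[ij[2]], 0.025, tolerance = 1e-9)
  # zero amplitude -> all-zero profile
  cfg0 <- quick_cfg(1)
  cfg0$evoked[[1]]$peak_amplitude_uA_mm3 <- 0
  expect_true(all(make_evoked_csd_truth(cfg0)$values == 0))
})

test_that("forward potential of a uniform slab matches the closed form", {
  sigma <- 0.3; r_mm <- 0.5; c0 <- 3; a <- 0.3; b <- 0.7  # mm
  anti <- function(h) (h * sqrt(h^2 + r_mm^2) + r_mm^2 * asinh(h / r_mm)) / 2
  phi_exact <- function(zi) {
    t1 <- anti(b - zi) - anti(a - zi)
    t2 <- (b - zi) * abs(b - zi) / 2 - (a - zi) * abs(a - zi) / 2
    c0 / (2 * sigma) * (t1 - t2)
  }
  zf <- seq(0, 1280, by = 1)
  vals <- matrix(as.numeric(zf >= 300 & zf <= 700) * c0, ncol = 1)
  prof <- depth_time_profile(zf, 0, vals, units = "uA_per_mm3")
  zout <- seq(0, 1280, by = 20)
  lfp <- forward_lfp_from_csd(prof, zout, sigma, 500)
  exact <- vapply(zout / 1000, phi_exact, numeric(1))
  expect_lt(max(abs(lfp$values[, 1] - exact)) / max(abs(exact)), 0.005)
})

test_that("forward model is linear and scales as 1/sigma", {
  cfg <- quick_cfg(3)
  t1 <- make_evoked_csd_truth(cfg)
  zout <- sim_depth_grid(cfg)
  f1 <- forward_lfp_from_csd(t1, zout, 0.3, 500)
  # zero CSD -> zero LFP
  zero <- depth_time_profile(t1$depth_um, t1$time_s, 0 * t1$values,
                             units = "uA_per_mm3")
  expect_true(all(forward_lfp_from_csd(zero, zout)$values == 0))
  # doubling sigma halves phi
  f2 <- forward_lfp_from_csd(t1, zout, 0.6, 500)
  expect_equal(f2$values, f1$values / 2, tolerance = 1e-12)
  # linearity in the CSD
  t3 <- depth_time_profile(t1$depth_um, t1$time_s, 2.5 * t1$values,
                           units = "uA_per_mm3")
  f3 <- forward_lfp_from_csd(t3, zout, 0.3, 500)
  expect_equal(f3$values, 2.5 * f1$values, tolerance = 1e-12)
})

test_that("identical seeds give identical sessions, different seeds differ", {
  s1 <- simulate_session(quick_cfg(5))
  s2 <- simulate_session(quick_cfg(5))
  s3 <- simulate_session(quick_cfg(6))
  expect_identical(s1$lfp$values, s2$lfp$values)
  expect_identical(s1$trials$onset_s, s2$trials$onset_s)
  expect_identical(s1$spikes$spike_time_s, s2$spikes$spike_time_s)
  expect_false(identical(s1$lfp$values, s3$lfp$values))
})

test_that("epileptiform configuration yields disjoint ground-truth intervals", {
  ep <- tibble::tibble(start_s = c(30, 70), duration_s = c(15, 12),
                       frequency_hz = c(2, 3), amplitude_mult = c(8, 8))
  s <- simulate_session(quick_cfg(7, duration_s = 120, epileptiform = ep,
                                  trials = list(n_tactile = 3, n_visual = 2)))
  iv <- s$truth$event_intervals
  expect_equal(nrow(iv), 2L)
  expect_true(all(iv$end_s[-nrow(iv)] < iv$start_s[-1]))
  expect_equal(iv$start_s, c(30, 70))
})

test_that("background noise has the configured RMS, spectrum and correlation", {
  set.seed(1)
  fs <- 1000
  K <- laminarlfp:::pink_noise_matrix(4, fs * 60, fs, 0.05,
                                      c(0, 200, 400, 600), 200)
  rms <- sqrt(rowMeans(K^2))
  expect_equal(rms, rep(0.05, 4), tolerance = 0.05)
  # empirical PSD tracks the exported theoretical curve
  sp <- stft_spectrogram(K[1, ], fs)
  sel <- sp$freq_hz >= 2 & sp$freq_hz <= 90
  ratio <- colMeans(sp$power)[sel] / pink_noise_psd(sp$freq_hz[sel], 0.05, fs)
  expect_equal(mean(ratio), 1, tolerance = 0.1)
  # exponential spatial correlation: rows 200 um apart at length 200 um
  expect_equal(cor(K[1, ], K[2, ]), exp(-1), tolerance = 0.1)
})

test_that("simulate_cohort applies group deltas deterministically", {
  base <- quick_cfg(1, trials = list(n_tactile = 2, n_visual = 1),
                    spikes = list(n_clusters = 2))
  coh <- simulate_cohort(base, list(evoked_amplitude_scale = 0.3,
                                    latency_shift_s = 0.005,
                                    gamma_amplitude_scale = 0.3),
                         n_per_group = 2, seed = 3)
  expect_equal(nrow(coh), 4L)
  expect_equal(sum(coh$group == "ko"), 2L)
  ctrl <- coh$session[[1]]$truth
  ko <- coh$session[[which(coh$group == "ko")[1]]]$truth
  expect_equal(ko$evoked[[1]]$peak_amplitude_uA_mm3,
               0.3 * ctrl$evoked[[1]]$peak_amplitude_uA_mm3)
  expect_equal(ko$evoked[[1]]$latency_s, ctrl$evoked[[1]]$latency_s + 0.005)
  expect_equal(ko$gamma_amplitude_mv, 0.3 * ctrl$gamma_amplitude_mv)
  coh2 <- simulate_cohort(base, list(evoked_amplitude_scale = 0.3,
                                     latency_shift_s = 0.005,
                                     gamma_amplitude_scale = 0.3),
                          n_per_group = 2, seed = 3)
  expect_identical(coh$session[[1]]$lfp$values, coh2$session[[1]]$lfp$values)
})
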