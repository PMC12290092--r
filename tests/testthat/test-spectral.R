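test_that("STFT finds pure tones and satisfies Parseval", {
  fs <- 2500
  tax <- (0:(fs * 12 - 1)) / fs
  sp <- stft_spectrogram(sin(2 * pi * 70 * tax), fs)
  expect_equal(sp$freq_hz[which.max(colMeans(sp$power))], 70)
  expect_equal(diff(sp$freq_hz)[1], 0.5)   # 1 / (2 s window)

  # DC signal: dominant bin at 0 Hz, nothing beyond the taper's main lobe
  spd <- stft_spectrogram(rep(3, fs * 4), fs)
  pm <- colMeans(spd$power)
  expect_equal(spd$freq_hz[which.max(pm)], 0)
  expect_lt(max(pm[-(1:2)]) / pm[1], 1e-20)

  # white noise: sum(power) * df ~ variance
  set.seed(21)
  w <- rnorm(fs * 12, sd = 0.7)
  spw <- stft_spectrogram(w, fs)
  expect_equal(sum(colMeans(spw$power)) * 0.5, 0.49, tolerance = 0.05)

  expect_error(stft_spectrogram(rnorm(100), fs), "shorter")
  expect_warning(stft_spectrogram(rnorm(fs * 10), fs, window_s = 2,
                                  step_s = 3), "gaps")
})

test_that("band-limited direct path equals the FFT path exactly", {
  set.seed(22)
  fs <- 1000
  x <- rnorm(fs * 8)
  full <- stft_spectrogram(x, fs)
  for (band in list(c(0.5, 10), c(30, 120))) {
    sub <- stft_spectrogram(x, fs, freq_range_hz = band)
    sel <- full$freq_hz >= band[1] - 1e-9 & full$freq_hz <= band[2] + 1e-9
    expect_equal(sub$power, full$power[, sel], tolerance = 1e-10)
    expect_equal(sub$freq_hz, full$freq_hz[sel])
  }
})

test_that("depth PSD uses the dB re 1 mV^2/Hz convention", {
  set.seed(23)
  fs <- 1000
  n <- fs * 30
  # white noise with variance fs/2 has flat PSD of 1 mV^2/Hz -> 0 dBmV
  x <- rnorm(n, sd = sqrt(fs / 2))
  lfp <- laminar_lfp(rbind(x, x / 2), fs, c(0, 40))
  psd <- depth_psd(lfp)
  sel <- psd$freq_hz >= 5 & psd$freq_hz <= 400
  expect_equal(mean(psd$power_dbmv[1, sel]), 0, tolerance = 0.3)
  # halving the amplitude lowers the PSD by 20*log10(2) = 6.02 dB
  expect_equal(mean(psd$power_dbmv[1, sel] - psd$power_dbmv[2, sel]),
               20 * log10(2), tolerance = 1e-9)
})

test_that("excluded windows do not contaminate the depth PSD", {
  set.seed(24)
  fs <- 1000
  n <- fs * 40
  x <- rnorm(n, sd = 0.05)
  x_loud <- x
  x_loud[(15 * fs):(20 * fs)] <- x_loud[(15 * fs):(20 * fs)] + 5
  mask <- exclusion_mask_from_events(
    tibble::tibble(start_s = 15, end_s = 20), pad_s = 2, bounds = c(0, 40))
  psd_clean <- depth_psd(laminar_lfp(matrix(x, 1), fs, 0), mask)
  psd_loud <- depth_psd(laminar_lfp(matrix(x_loud, 1), fs, 0), mask)
  expect_equal(psd_loud$power_dbmv, psd_clean$power_dbmv, tolerance = 1e-9)
  expect_error(depth_psd(laminar_lfp(matrix(x, 1), fs, 0),
                         exclusion_mask_from_events(
                           tibble::tibble(start_s = 0, end_s = 40),
                           0, c(0, 40))),
               "excluded")
})

test_that("band_power snaps inclusive edges and averages dB values", {
  freq <- seq(0, 500, by = 0.5)
  pd <- structure(list(depth_um = c(100, 200),
                       freq_hz = freq,
                       power_dbmv = matrix(-20, 2, length(freq))),
                  class = "depth_psd")
  expect_equal(band_power(pd, c(30, 120)), -20)
  expect_equal(length(laminarlfp:::snap_band_bins(freq, c(30, 120))), 181L)
  # injected 70 Hz tone raises gamma but not the low band
  set.seed(25)
  fs <- 1000
  n <- fs * 30
  tone <- 0.05 * sin(2 * pi * 70 * (0:(n - 1)) / fs)
  noise <- rnorm(n, sd = 0.05)
  p0 <- depth_psd(laminar_lfp(matrix(noise, 1), fs, 0))
  p1 <- depth_psd(laminar_lfp(matrix(noise + tone, 1), fs, 0))
  # tone power concentrates in a few of the 181 gamma bins: band mean rises
  # modestly, the 70-Hz bin itself by tens of dB
  expect_gt(band_power(p1, c(30, 120)) - band_power(p0, c(30, 120)), 0.2)
  i70 <- which.min(abs(p0$freq_hz - 70))
  expect_gt(p1$power_dbmv[1, i70] - p0$power_dbmv[1, i70], 15)
  expect_equal(band_power(p1, c(0.5, 10)), band_power(p0, c(0.5, 10)),
               tolerance = 0.02)
})

test_that("stimulus PSD change is a calibrated ratio statistic", {
  fs <- 500
  n <- fs * 120
  tax <- (0:(n - 1)) / fs
  onsets <- seq(10, 100, by = 10)
  trials <- trial_table(seq_along(onsets), rep("visual", length(onsets)),
                        onsets, 1L, "")
  # tone whose power exactly doubles during the stimulus window
  stim <- rowSums(vapply(onsets, function(o) tax >= o & tax < o + 5,
                         numeric(n))) > 0
  x <- ifelse(stim, sqrt(2), 1) * sin(2 * pi * 50 * tax)
  lfp <- laminar_lfp(matrix(x, 1), fs, 0)
  ch <- stimulus_psd_change(lfp, trials, stim_window_s = c(1, 4),
                            base_window_s = c(-1.9, -1.1))
  i50 <- which.min(abs(ch$freq_hz - 50))
  expect_equal(ch$percent[1, i50], 100, tolerance = 1)
  # identical stim and baseline -> 0%
  x0 <- sin(2 * pi * 50 * tax)
  ch0 <- stimulus_psd_change(laminar_lfp(matrix(x0, 1), fs, 0), trials,
                             c(1, 4), c(-1.9, -1.1))
  expect_equal(ch0$percent[1, i50], 0, tolerance = 1e-9)
  # invariant under rescaling the whole recording
  ch2 <- stimulus_psd_change(laminar_lfp(matrix(3 * x, 1), fs, 0), trials,
                             c(1, 4), c(-1.9, -1.1))
  expect_equal(ch2$percent[1, i50], ch$percent[1, i50], tolerance = 1e-9)
  # bins with zero baseline power are flagged NA (silent baseline)
  x_gated <- ifelse(stim, 1, 0) * sin(2 * pi * 50 * tax)
  ch_gated <- stimulus_psd_change(laminar_lfp(matrix(x_gated, 1), fs, 0),
                                  trials, c(1, 4), c(-1.9, -1.1))
  expect_true(anyNA(ch_gated$percent))
})
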