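test_that("write_session / read_session round-trips all objects exactly", {
  dir <- withr::local_tempdir()
  mv_per_bit <- 0.00195
  # values on the int16 grid so quantisation is exact
  vals <- matrix(c(-3, -1, 0, 1, 2, 100, 7, -8) * mv_per_bit, nrow = 2)
  geom <- channel_geometry(1:2, depth_um = c(0, 20))
  lfp <- laminar_lfp(vals, 2500, c(0, 20), start_time_s = 1.5)
  trials <- trial_table(1:2, c("tactile", "visual"), c(10, 20.25),
                        c(2L, 1L), c("isi=0.5", "grating"))
  spikes <- spike_table(c(1L, 1L, 2L), c(0.5, 1.25, 3), c(150, 150, 700))
  write_session(dir, geom, lfp, trials, spikes, mv_per_bit)

  back <- read_session(dir)
  expect_equal(back$geometry$depth_um, geom$depth_um)
  expect_equal(back$lfp$values, vals)
  expect_equal(back$lfp$sampling_rate_hz, 2500)
  expect_equal(back$lfp$start_time_s, 1.5)
  expect_equal(as.data.frame(back$trials), as.data.frame(trials))
  expect_equal(as.data.frame(back$spikes), as.data.frame(spikes))

  # deterministic bytes
  dir2 <- withr::local_tempdir()
  write_session(dir2, geom, lfp, trials, spikes, mv_per_bit)
  expect_identical(readBin(file.path(dir, "lfp.bin"), raw(), 1000),
                   readBin(file.path(dir2, "lfp.bin"), raw(), 1000))
})

test_that("int16 samples are scaled to millivolts by the sidecar factor", {
  dir <- withr::local_tempdir()
  geom <- channel_geometry(1L, 0)
  lfp <- laminar_lfp(matrix(100 * 0.00195, 1, 1), 2500, 0)
  write_session(dir, geom, lfp, trial_table(), spike_table(), 0.00195)
  back <- read_session(dir)
  expect_equal(back$lfp$values[1, 1], 0.195)
})

test_that("a sidecar contradicting the binary payload is a hard error", {
  dir <- withr::local_tempdir()
  geom <- channel_geometry(1:3, c(0, 20, 40))
  lfp <- laminar_lfp(matrix(0, 3, 10), 2500, c(0, 20, 40))
  write_session(dir, geom, lfp, trial_table(), spike_table())
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  meta$n_channels <- 4
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  expect_error(read_session(dir), "n_channels|channel count")
})

test_that("invalid sessions are refused and missing tables degrade gracefully", {
  dir <- withr::local_tempdir()
  geom <- channel_geometry(1L, 0)
  expect_error(
    laminar_lfp(matrix(NaN, 1, 4), 2500, 0),
    "finite")
  lfp <- laminar_lfp(matrix(0, 1, 4), 2500, 0)
  write_session(dir, geom, lfp, trial_table(), spike_table())
  # empty spike table -> header-only file
  expect_equal(length(readLines(file.path(dir, "spikes.tsv"))), 1L)
  file.remove(file.path(dir, "spikes.tsv"))
  expect_warning(back <- read_session(dir), "spikes")
  expect_equal(nrow(back$spikes), 0L)
})

test_that("reject_channels flags dead and extreme-RMS channels only", {
  set.seed(42)
  # one constant channel among 20 noisy ones
  vals <- matrix(rnorm(20 * 1000, sd = 0.1), 20)
  vals[7, ] <- 0
  geom <- channel_geometry(1:20, seq(0, 380, by = 20))
  lfp <- laminar_lfp(vals, 2500, geom$depth_um)
  out <- suppressMessages(reject_channels(lfp, geom))
  expect_identical(which(!out$included), 7L)

  # fixed 5-channel fixture with one channel at 100x RMS; hand-computed
  # log-RMS MAD decision: deviations of the 4 normal channels are far
  # below 5 MADs, log(100) = 4.6 is far above
  set.seed(7)
  v5 <- matrix(rnorm(5 * 2000, sd = 0.1), 5)
  v5[3, ] <- v5[3, ] * 100
  log_rms <- 0.5 * log(rowMeans(v5^2))
  dev <- abs(log_rms - median(log_rms))
  expect_true(dev[3] > 5 * mad(log_rms))
  expect_true(all(dev[-3] < 5 * mad(log_rms)))
  g5 <- channel_geometry(1:5, seq(0, 80, by = 20))
  out5 <- suppressMessages(reject_channels(laminar_lfp(v5, 2500, g5$depth_um), g5))
  expect_identical(which(!out5$included), 3L)

  expect_error(reject_channels(laminar_lfp(matrix(0, 1, 10), 2500, 0),
                               channel_geometry(1L, 0)),
               "at least 2")
})

test_that("reject_channels false-positive rate is below 1% on homogeneous noise", {
  set.seed(99)
  n_rej <- 0L; n_tot <- 0L
  for (rep in 1:50) {
    vals <- matrix(rnorm(20 * 500, sd = 0.1), 20)
    geom <- channel_geometry(1:20, seq(0, 380, by = 20))
    out <- suppressMessages(reject_channels(laminar_lfp(vals, 2500, geom$depth_um), geom))
    n_rej <- n_rej + sum(!out$included)
    n_tot <- n_tot + 20L
  }
  expect_lt(n_rej / n_tot, 0.01)
})

test_that("average_same_depth averages included channels per depth row", {
  geom <- channel_geometry(1:3, c(500, 500, 600))
  vals <- rbind(rep(1, 5), rep(3, 5), rep(7, 5))
  lfp <- laminar_lfp(vals, 2500, geom$depth_um)
  out <- average_same_depth(lfp, geom)
  expect_equal(out$depth_um, c(500, 600))
  expect_equal(out$values[1, ], rep(2, 5))
  expect_equal(out$values[2, ], rep(7, 5))  # single channel passes through

  # depth vector {20, 20, 40} -> {20, 40}
  g2 <- channel_geometry(1:3, c(20, 20, 40))
  out2 <- average_same_depth(laminar_lfp(vals, 2500, g2$depth_um), g2)
  expect_equal(out2$depth_um, c(20, 40))

  # idempotent on already-averaged input
  out3 <- average_same_depth(out, channel_geometry(1:2, out$depth_um))
  expect_equal(out3$values, out$values)

  # rows whose channels are all excluded are dropped
  g3 <- channel_geometry(1:3, c(20, 20, 40), included = c(TRUE, TRUE, FALSE))
  out4 <- suppressMessages(average_same_depth(laminar_lfp(vals, 2500, g3$depth_um), g3))
  expect_equal(out4$depth_um, 20)
})
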