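test_that("forward matrix reproduces the analytic slab potential", {
  depths <- seq(0, 1260, by = 20)
  cfg <- csd_config()
  F_mat <- build_spline_forward_matrix(depths, cfg)
  c0 <- 2
  phi <- F_mat %*% rep(c0, length(depths))
  # closed-form slab over the full electrode span
  sigma <- 0.3; r_mm <- 0.5; a <- 0; b <- 1.26
  anti <- function(h) (h * sqrt(h^2 + r_mm^2) + r_mm^2 * asinh(h / r_mm)) / 2
  exact <- vapply(depths / 1000, function(zi) {
    t1 <- anti(b - zi) - anti(a - zi)
    t2 <- (b - zi) * abs(b - zi) / 2 - (a - zi) * abs(a - zi) / 2
    c0 / (2 * sigma) * (t1 - t2)
  }, numeric(1))
  expect_lt(max(abs(phi - exact)) / max(abs(exact)), 0.005)
  # zero CSD -> zero potential
  expect_equal(as.numeric(F_mat %*% numeric(length(depths))),
               numeric(length(depths)))
})

test_that("forward matrix is translation-invariant away from the edges", {
  depths <- seq(0, 1260, by = 20)
  F_mat <- build_spline_forward_matrix(depths, csd_config())
  n <- length(depths)
  i1 <- 30L; i2 <- 34L   # interior rows
  for (off in -5:5) {
    expect_equal(F_mat[i1, i1 + off], F_mat[i2, i2 + off],
                 tolerance = 1e-6)
  }
  expect_error(build_spline_forward_matrix(c(0, 20, 50, 90), csd_config()),
               "uniform")
  expect_error(build_spline_forward_matrix(c(0, 20, 40), csd_config()),
               "at least 4")
})

test_that("spline iCSD inverts the quadrature forward model", {
  # smooth Gaussian sink/source truth, 64 rows at 20 um, R = 0.5 mm
  cfg <- sim_config(seed = 1, n_depth_rows = 64, depth_spacing_um = 20)
  truth <- make_evoked_csd_truth(cfg)
  elec <- sim_depth_grid(cfg)
  phi <- forward_lfp_from_csd(truth, elec, 0.3, 500)
  est <- estimate_csd(phi, csd_config(0.3, 500))
  tru <- apply(truth$values, 2,
               function(col) approx(truth$depth_um, col, xout = elec)$y)
  expect_lt(sqrt(sum((est$values - tru)^2) / sum(tru^2)), 0.05)
  # peak depth within one grid step
  tj <- which.min(apply(tru, 2, min))
  expect_lte(abs(elec[which.min(est$values[, tj])] -
                 elec[which.min(tru[, tj])]), 20)
  # zero LFP -> zero CSD; scaling LFP by 3 scales CSD by 3
  zero <- depth_time_profile(elec, phi$time_s, 0 * phi$values, units = "mV")
  expect_true(all(abs(estimate_csd(zero)$values) < 1e-12))
  phi3 <- depth_time_profile(elec, phi$time_s, 3 * phi$values, units = "mV")
  expect_equal(estimate_csd(phi3, csd_config(0.3, 500))$values,
               3 * est$values, tolerance = 1e-9)
})

test_that("spline iCSD approaches the second-difference estimator for large R", {
  cfg <- sim_config(seed = 2, n_depth_rows = 64, depth_spacing_um = 20)
  truth <- make_evoked_csd_truth(cfg)
  elec <- sim_depth_grid(cfg)
  r_um <- 5e4   # R = 50 mm >> 1.26 mm probe span
  phi <- forward_lfp_from_csd(truth, elec, 0.3, r_um)
  est <- estimate_csd(phi, csd_config(0.3, r_um))
  P <- phi$values
  h_mm <- 0.02
  secdiff <- -0.3 * (P[1:62, ] - 2 * P[2:63, ] + P[3:64, ]) / h_mm^2
  interior <- 2:63
  rel <- sqrt(mean((est$values[interior, ] - secdiff)^2)) /
    sqrt(mean(secdiff^2))
  expect_lt(rel, 0.10)
})

test_that("depth smoothing matches the sampled Gaussian and conserves mass", {
  depths <- seq(0, 1260, by = 20)
  n <- length(depths)
  tt <- 0
  # constant profile unchanged
  const <- depth_time_profile(depths, tt, matrix(4, n, 1), "uA_per_mm3")
  expect_equal(smooth_csd_depth(const, 0.1)$values, const$values,
               tolerance = 1e-12)
  # interior unit impulse -> renormalised sampled Gaussian (SD 100 um)
  imp <- matrix(0, n, 1); imp[32, 1] <- 1
  sm <- smooth_csd_depth(depth_time_profile(depths, tt, imp, "uA_per_mm3"), 0.1)
  half <- ceiling(4 * 0.1 / 0.02)
  kern <- exp(-0.5 * ((-half:half) * 20 / 100)^2); kern <- kern / sum(kern)
  expect_equal(sm$values[32 + (-half:half), 1], kern, tolerance = 1e-12)
  # smoothing reduces total variation; depth-sum conserved
  set.seed(3)
  rough <- depth_time_profile(depths, tt, matrix(rnorm(n), n, 1), "uA_per_mm3")
  smr <- smooth_csd_depth(rough, 0.1)
  tv <- function(v) sum(abs(diff(v)))
  expect_lt(tv(smr$values[, 1]), tv(rough$values[, 1]))
  expect_equal(sum(smr$values), sum(rough$values), tolerance = 1e-9)
  expect_error(smooth_csd_depth(rough, 0), "positive")
})

test_that("peak extraction returns the most negative deflection, earliest tie", {
  depths <- seq(300, 500, by = 20)
  tms <- seq(0, 0.1, by = 0.0001)   # 27.2 ms falls on the grid
  vals <- matrix(0, length(depths), length(tms))
  tr <- -4.74 * exp(-0.5 * ((tms - 0.0272) / 0.005)^2)
  vals[6, ] <- tr   # row at 400 um
  prof <- depth_time_profile(depths, tms, vals, "uA_per_mm3")
  pk <- extract_peak_response(prof, 400, c(0, 0.1))
  expect_equal(pk$peak_amplitude_uA_mm3, -4.74, tolerance = 1e-9)
  expect_equal(pk$peak_time_ms, 27.2, tolerance = 1e-6)

  # monotone increasing trace -> boundary minimum at window start
  vals2 <- matrix(rep(seq_along(tms), each = length(depths)),
                  length(depths))
  pk2 <- extract_peak_response(
    depth_time_profile(depths, tms, vals2, "uA_per_mm3"), 400, c(0, 0.1))
  expect_equal(pk2$peak_time_ms, 0)

  # two equal minima at 20 and 40 ms -> earliest wins
  vals3 <- matrix(0, length(depths), length(tms))
  vals3[6, c(which.min(abs(tms - 0.020)), which.min(abs(tms - 0.040)))] <- -1
  pk3 <- extract_peak_response(
    depth_time_profile(depths, tms, vals3, "uA_per_mm3"), 400, c(0, 0.1))
  expect_equal(pk3$peak_time_ms, 20)

  expect_error(extract_peak_response(prof, 400, c(0.5, 0.6)),
               "no time samples")
})
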