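# Spline inverse current-source-density estimation.
#
# Electrostatic forward model: at each depth z the CSD C(z) is assumed
# uniform over a disc of radius R centred on the probe axis, with
# homogeneous isotropic conductivity sigma. The potential a disc-distributed
# CSD generates at electrode depth z_i is
#
#   phi(z_i) = (1 / (2 sigma)) * Int C(z) [ sqrt((z - z_i)^2 + R^2) - |z - z_i| ] dz
#
# With depths in mm, C in uA/mm^3 and sigma in S/m the integral comes out in
# mV directly (1 mV * S/m / mm^2 = 1 uA/mm^3). The spline iCSD variant
# interpolates C between electrode contacts with a natural cubic spline and
# assumes zero CSD outside the outermost contacts; the forward matrix F maps
# the CSD knot values to electrode potentials and is inverted per time
# sample.

#' CSD estimation configuration
#'
#' @param sigma_S_per_m Extracellular conductivity in S/m; 0.3 is the
#'   standard value for cortical tissue.
#' @param disk_radius_um Radius R of the cylindrical source model, in
#'   micrometres. Not identifiable from the recording itself; the default,
#'   500 um, is the order of a cortical column. All results should cite the
#'   R used.
#' @param gaussian_sd_mm Depth-smoothing Gaussian SD (mm) for
#'   [smooth_csd_depth()].
#' @param spline_endpoint Endpoint condition of the interpolating spline;
#'   only `"natural"` is implemented.
#' @return A list of class `csd_config`.
#' @export
csd_config <- function(sigma_S_per_m = 0.3, disk_radius_um = 500,
                       gaussian_sd_mm = 0.1, spline_endpoint = "natural") {
  stopifnot_scalar_number(sigma_S_per_m, "sigma_S_per_m", positive = TRUE)
  stopifnot_scalar_number(disk_radius_um, "disk_radius_um", positive = TRUE)
  stopifnot_scalar_number(gaussian_sd_mm, "gaussian_sd_mm", positive = TRUE)
  spline_endpoint <- match.arg(spline_endpoint, "natural")
  structure(list(sigma_S_per_m = sigma_S_per_m,
                 disk_radius_um = disk_radius_um,
                 gaussian_sd_mm = gaussian_sd_mm,
                 spline_endpoint = spline_endpoint),
            class = "csd_config")
}

# Disc-source kernel evaluated at electrode depths z_i (rows) for source
# depths z (columns); all in mm. Excludes the 1/(2 sigma) factor.
csd_disk_kernel <- function(z_elec_mm, z_src_mm, r_mm) {
  dz <- outer(z_elec_mm, z_src_mm, `-`)
  sqrt(dz^2 + r_mm^2) - abs(dz)
}

#' Build the spline-iCSD forward matrix
#'
#' Computes the matrix `F` mapping CSD values at the electrode depths
#' (natural-cubic-spline interpolated between contacts, zero outside the
#' outermost contacts) to the potentials those sources generate at the same
#' depths under the disc kernel. Entries are computed by per-segment
#' Gauss-Legendre quadrature of each cardinal spline basis function against
#' the kernel; the kernel's |z - z_i| kink always falls on a segment
#' boundary, so each segment integrand is smooth.
#'
#' @param depths_um Uniform, strictly increasing electrode depths (>= 4).
#' @param cfg A [csd_config()].
#' @param n_quad Gauss-Legendre nodes per inter-electrode segment.
#' @return Matrix `F` (mV per uA/mm^3), with attributes `depths_um` and
#'   `condition_number`.
#' @export
build_spline_forward_matrix <- function(depths_um, cfg = csd_config(),
                                        n_quad = 20L) {
  n <- length(depths_um)
  if (n < 4L) abort("spline iCSD needs at least 4 electrode depths.")
  if (!is_uniform_grid(depths_um, tol = 1e-6)) {
    abort("electrode depth grid must be uniform.")
  }
  z <- depths_um / 1000   # mm
  r_mm <- cfg$disk_radius_um / 1000
  gl <- gauss_legendre(n_quad)

  # Quadrature nodes over every segment [z_j, z_{j+1}].
  h <- diff(z)
  nodes <- as.vector(vapply(seq_len(n - 1L), function(j) {
    0.5 * (z[j] + z[j + 1L]) + 0.5 * h[j] * gl$x
  }, numeric(n_quad)))
  wts <- as.vector(vapply(seq_len(n - 1L), function(j) 0.5 * h[j] * gl$w,
                          numeric(n_quad)))

  # Cardinal natural-spline basis evaluated at the quadrature nodes.
  basis <- matrix(0, length(nodes), n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- 1
    basis[, j] <- splinefun(z, e, method = "natural")(nodes)
  }

  K <- csd_disk_kernel(z, nodes, r_mm)            # n x npts
  F_mat <- (K %*% (wts * basis)) / (2 * cfg$sigma_S_per_m)
  kappa <- kappa(F_mat, exact = FALSE)
  if (kappa > 1e8) {
    abort(sprintf(
      "forward matrix condition number %.3g exceeds 1e8; use a larger disk radius or fewer depth rows.",
      kappa))
  }
  attr(F_mat, "depths_um") <- as.double(depths_um)
  attr(F_mat, "condition_number") <- kappa
  F_mat
}

#' Estimate CSD from a laminar LFP profile
#'
#' Inverts the spline forward model per time sample: solves `F c = phi` with
#' a single LU factorisation reused across all time columns. Input must be a
#' potential profile in mV on a uniform depth grid; output is CSD in uA/mm^3
#' on the same grid.
#'
#' @param lfp_profile A [depth_time_profile()] with units `"mV"`.
#' @param cfg A [csd_config()].
#' @return A [depth_time_profile()] with units `"uA_per_mm3"`.
#' @export
estimate_csd <- function(lfp_profile, cfg = csd_config()) {
  if (!inherits(lfp_profile, "depth_time_profile") ||
      lfp_profile$units != "mV") {
    abort("estimate_csd expects a depth_time_profile in mV.")
  }
  F_mat <- build_spline_forward_matrix(lfp_profile$depth_um, cfg)
  csd <- solve(F_mat, lfp_profile$values)
  depth_time_profile(lfp_profile$depth_um, lfp_profile$time_s, csd,
                     units = "uA_per_mm3")
}

#' Smooth a CSD profile along depth
#'
#' Convolves each time sample with a discrete Gaussian along depth. The
#' kernel is truncated at +/- 4 SD and renormalised to unit sum; boundaries
#' use symmetric (half-sample) reflection, which preserves the depth-sum of
#' the profile and avoids the edge attenuation zero padding would cause at
#' the pial surface.
#'
#' @param csd A [depth_time_profile()].
#' @param gaussian_sd_mm Gaussian SD in mm (default 0.1).
#' @return The smoothed profile, same grid and units.
#' @export
smooth_csd_depth <- function(csd, gaussian_sd_mm = 0.1) {
  if (!inherits(csd, "depth_time_profile")) {
    abort("smooth_csd_depth expects a depth_time_profile.")
  }
  stopifnot_scalar_number(gaussian_sd_mm, "gaussian_sd_mm", positive = TRUE)
  dz_mm <- if (length(csd$depth_um) > 1) diff(csd$depth_um)[1] / 1000 else
    abort("smoothing needs at least 2 depth rows.")
  half <- max(1L, ceiling(4 * gaussian_sd_mm / dz_mm))
  kern <- exp(-0.5 * ((-half:half) * dz_mm / gaussian_sd_mm)^2)
  kern <- kern / sum(kern)
  n <- length(csd$depth_um)
  # symmetric (half-sample) reflection indices: x[0] -> x[1], x[n+1] -> x[n]
  idx <- c(rev(seq_len(half)), seq_len(n), n + 1L - seq_len(half))
  padded <- csd$values[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(csd$values))
  for (k in seq_along(kern)) {
    out <- out + kern[k] * padded[(k - 1L) + seq_len(n), , drop = FALSE]
  }
  depth_time_profile(csd$depth_um, csd$time_s, out, units = csd$units)
}

#' Extract the peak (most negative) CSD response
#'
#' Returns the amplitude and latency of the strongest current sink at a
#' given depth within a search window: the minimum value of the profile row
#' nearest `depth_um` over the window, with ties broken by the earliest
#' time.
#'
#' @param csd_avg A [depth_time_profile()] (typically trial-averaged,
#'   smoothed CSD with trial-relative time).
#' @param depth_um Target depth in micrometres (nearest grid row is used).
#' @param search_window_s Length-2 window `(t0, t1)` in seconds relative to
#'   the profile's time axis.
#' @return A tibble with `depth_um_used`, `peak_amplitude_uA_mm3`,
#'   `peak_time_ms`.
#' @export
extract_peak_response <- function(csd_avg, depth_um,
                                  search_window_s = c(0, 0.2)) {
  if (!inherits(csd_avg, "depth_time_profile")) {
    abort("extract_peak_response expects a depth_time_profile.")
  }
  i <- nearest_depth_row(csd_avg$depth_um, depth_um)
  sel <- which(csd_avg$time_s >= search_window_s[1] &
               csd_avg$time_s <= search_window_s[2])
  if (length(sel) == 0L) abort("search window contains no time samples.")
  trace <- csd_avg$values[i, sel]
  j <- sel[which.min(trace)]   # which.min returns the first (earliest) minimum
  tibble(
    depth_um_used = csd_avg$depth_um[i],
    peak_amplitude_uA_mm3 = csd_avg$values[i, j],
    peak_time_ms = csd_avg$time_s[j] * 1000
  )
}
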