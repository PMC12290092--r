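#' Depth-by-time profile
#'
#' The common container for trial-averaged LFP (mV) and estimated or
#' ground-truth CSD (uA/mm^3): a matrix over a uniform depth grid and a
#' uniform time grid (absolute or trial-relative seconds).
#'
#' @param depth_um Strictly increasing uniform depth grid (micrometres).
#' @param time_s Uniform time grid (seconds).
#' @param values Numeric matrix, depth x time.
#' @param units `"mV"` or `"uA_per_mm3"`.
#' @return An object of class `depth_time_profile`.
#' @export
depth_time_profile <- function(depth_um, time_s, values,
                               units = c("mV", "uA_per_mm3")) {
  units <- match.arg(units)
  values <- as.matrix(values)
  if (nrow(values) != length(depth_um) || ncol(values) != length(time_s)) {
    abort("values must be depth x time.")
  }
  if (!is_uniform_grid(depth_um) || !is_uniform_grid(time_s)) {
    abort("depth and time grids must be uniform.")
  }
  if (length(depth_um) > 1 && is.unsorted(depth_um, strictly = TRUE)) {
    abort("depth_um must be strictly increasing.")
  }
  if (any(!is.finite(values))) abort("profile values must be finite.")
  structure(
    list(depth_um = as.double(depth_um), time_s = as.double(time_s),
         values = values, units = units),
    class = "depth_time_profile"
  )
}

#' @export
print.depth_time_profile <- function(x, ...) {
  cat(sprintf("<depth_time_profile> %d depths x %d times [%s], depth %g-%g um, t %g-%g s\n",
              length(x$depth_um), length(x$time_s), x$units,
              min(x$depth_um), max(x$depth_um), min(x$time_s), max(x$time_s)))
  invisible(x)
}

#' Tidy a depth-time profile into long format
#'
#' @param x A [depth_time_profile()].
#' @param ... Unused.
#' @return A tibble with columns `depth_um`, `time_s`, `value`, `units`.
#' @export
tidy.depth_time_profile <- function(x, ...) {
  tibble(
    depth_um = rep(x$depth_um, times = length(x$time_s)),
    time_s = rep(x$time_s, each = length(x$depth_um)),
    value = as.vector(x$values),
    units = x$units
  )
}

# Index of the profile/LFP row closest to a requested depth.
nearest_depth_row <- function(depth_grid, depth_um, max_dist_um = Inf,
                              quiet = FALSE) {
  i <- which.min(abs(depth_grid - depth_um))
  d <- abs(depth_grid[i] - depth_um)
  if (d > max_dist_um) {
    abort(sprintf("no depth row within %g um of %g um.", max_dist_um, depth_um))
  }
  if (d > 0 && !quiet) {
    inform(sprintf("using depth row at %g um for requested %g um.",
                   depth_grid[i], depth_um))
  }
  i
}
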