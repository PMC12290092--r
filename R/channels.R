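#' Flag broken or out-of-brain channels
#'
#' Marks channels whose log root-mean-square amplitude is a robust outlier
#' among all channels, or whose variance is exactly zero (dead channels).
#' The rule: compute `log(RMS)` per channel, then flag channels deviating
#' from the median by more than `mad_k` median absolute deviations (MAD,
#' scaled by 1.4826 for normal consistency). This is a deliberately
#' parameter-light stand-in for toolbox-specific broken-channel heuristics.
#'
#' @param lfp A per-channel [laminar_lfp()] (rows = channels, matching
#'   `geometry` rows).
#' @param geometry A [channel_geometry()].
#' @param mad_k Rejection threshold in MADs (default 5).
#' @return The geometry with `included` set to `FALSE` for rejected channels.
#' @export
reject_channels <- function(lfp, geometry, mad_k = 5.0) {
  geometry <- validate_channel_geometry(geometry)
  if (nrow(lfp$values) != nrow(geometry)) {
    abort("LFP rows must match geometry channels.")
  }
  if (nrow(geometry) < 2L) {
    abort("channel rejection needs at least 2 channels.")
  }
  stopifnot_scalar_number(mad_k, "mad_k", positive = TRUE)
  v <- apply(lfp$values, 1, stats::var)
  dead <- v == 0
  log_rms <- rep(NA_real_, length(v))
  log_rms[!dead] <- 0.5 * log(rowMeans(lfp$values[!dead, , drop = FALSE]^2))
  med <- median(log_rms, na.rm = TRUE)
  scale <- mad(log_rms, center = med, na.rm = TRUE)
  if (is.na(scale) || scale == 0) {
    # degenerate spread (e.g. many identical channels): only the zero-variance
    # rule can act
    outlier <- rep(FALSE, length(v))
  } else {
    outlier <- abs(log_rms - med) > mad_k * scale
    outlier[is.na(outlier)] <- FALSE
  }
  bad <- dead | outlier
  if (any(bad)) {
    inform(sprintf("reject_channels: flagged %d of %d channels.",
                   sum(bad), length(bad)))
  }
  geometry$included <- geometry$included & !bad
  validate_channel_geometry(geometry)
}

#' Average channels sharing a depth row
#'
#' Contacts at the same cortical depth carry the same laminar signal;
#' averaging them improves signal quality. Produces one LFP row per distinct
#' depth among included channels (arithmetic mean of the included channels at
#' that depth); depths whose channels are all excluded are dropped.
#'
#' @param lfp A per-channel [laminar_lfp()].
#' @param geometry Matching [channel_geometry()].
#' @return A per-depth-row [laminar_lfp()], depths strictly increasing.
#' @export
average_same_depth <- function(lfp, geometry) {
  geometry <- validate_channel_geometry(geometry)
  if (nrow(lfp$values) != nrow(geometry)) {
    abort("LFP rows must match geometry channels.")
  }
  keep <- geometry$included
  if (all(keep) && !anyDuplicated(geometry$depth_um) &&
      !is.unsorted(geometry$depth_um, strictly = TRUE)) {
    return(lfp)   # already one included channel per depth row, in order
  }
  depths <- sort(unique(geometry$depth_um[keep]))
  dropped <- setdiff(unique(geometry$depth_um), depths)
  if (length(dropped) > 0) {
    inform(sprintf("average_same_depth: dropping %d depth row(s) with no included channel.",
                   length(dropped)))
  }
  out <- matrix(0, nrow = length(depths), ncol = ncol(lfp$values))
  for (k in seq_along(depths)) {
    rows <- which(keep & geometry$depth_um == depths[k])
    out[k, ] <- if (length(rows) == 1L) lfp$values[rows, ] else
      colMeans(lfp$values[rows, , drop = FALSE])
  }
  laminar_lfp(out, lfp$sampling_rate_hz, depths, lfp$start_time_s)
}
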