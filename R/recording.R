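#' Channel geometry of a laminar probe
#'
#' Describes where each recording channel sits on the probe: its depth below
#' the pial surface (micrometres, increasing downward) and its lateral
#' position across the probe face. Channels sharing an identical `depth_um`
#' form a "depth row"; rows are the spatial unit of all laminar analyses
#' (LFP averaging, iCSD, layer assignment).
#'
#' @param channel_index Integer channel ids, unique.
#' @param depth_um Depth below pia in micrometres, finite and >= 0.
#' @param lateral_um Lateral position in micrometres (default 0).
#' @param included Logical usability flag per channel (default `TRUE`).
#' @return A tibble of class `channel_geometry` with one row per channel.
#' @examples
#' channel_geometry(1:4, depth_um = c(0, 0, 20, 20), lateral_um = c(0, 32, 0, 32))
#' @export
channel_geometry <- function(channel_index, depth_um, lateral_um = 0,
                             included = TRUE) {
  geom <- tibble(
    channel_index = as.integer(channel_index),
    depth_um = as.double(depth_um),
    lateral_um = rep_len(as.double(lateral_um), length(channel_index)),
    included = rep_len(as.logical(included), length(channel_index))
  )
  validate_channel_geometry(geom)
}

validate_channel_geometry <- function(geom) {
  if (anyDuplicated(geom$channel_index)) abort("channel_index must be unique.")
  if (any(!is.finite(geom$depth_um)) || any(geom$depth_um < 0)) {
    abort("depth_um must be finite and >= 0.")
  }
  if (!any(geom$included)) abort("at least one channel must be included.")
  class(geom) <- c("channel_geometry", class(tibble()))
  geom
}

#' Depth-ordered multichannel LFP
#'
#' A matrix of local field potential in millivolts, one row per channel or
#' depth row, one column per sample, together with its sampling rate, start
#' time and per-row depth. The LFP band of interest here is 0.5-100 Hz
#' sampled at 2.5 kHz, but any rate is accepted.
#'
#' @param values Numeric matrix, rows = depths, columns = samples, in mV.
#' @param sampling_rate_hz Sampling rate in Hz (> 0).
#' @param depth_um Per-row depth vector (micrometres); strictly increasing
#'   when rows represent depth rows.
#' @param start_time_s Session time of the first sample (seconds).
#' @return An object of class `laminar_lfp`.
#' @export
laminar_lfp <- function(values, sampling_rate_hz, depth_um, start_time_s = 0) {
  if (!is.matrix(values)) values <- as.matrix(values)
  stopifnot_scalar_number(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  stopifnot_scalar_number(start_time_s, "start_time_s")
  if (nrow(values) != length(depth_um)) {
    abort("row count of values must equal length of depth_um.")
  }
  if (any(!is.finite(values))) abort("LFP values must all be finite.")
  if (is.unsorted(depth_um, strictly = FALSE)) {
    abort("depth_um must be non-decreasing.")
  }
  structure(
    list(values = values, sampling_rate_hz = as.double(sampling_rate_hz),
         depth_um = as.double(depth_um), start_time_s = as.double(start_time_s)),
    class = "laminar_lfp"
  )
}

#' @export
print.laminar_lfp <- function(x, ...) {
  cat(sprintf(
    "<laminar_lfp> %d rows x %d samples @ %g Hz, depths %g-%g um, t0 = %g s\n",
    nrow(x$values), ncol(x$values), x$sampling_rate_hz,
    min(x$depth_um), max(x$depth_um), x$start_time_s))
  invisible(x)
}

# Time stamps of LFP samples (seconds, session clock).
lfp_times <- function(lfp) {
  lfp$start_time_s + (seq_len(ncol(lfp$values)) - 1L) / lfp$sampling_rate_hz
}

lfp_duration <- function(lfp) ncol(lfp$values) / lfp$sampling_rate_hz

#' Trial table
#'
#' One row per stimulus trial: onset of the first stimulus (seconds, session
#' clock), modality and stimulus annotation. The reference design interleaves
#' 50 tactile trials (two 20-ms air puffs, 500 ms apart) and 50 visual trials
#' (5-s drifting gratings) in randomised order with 3-5 s inter-trial
#' intervals.
#'
#' @param trial_id Integer trial ids.
#' @param modality Character, `"tactile"` or `"visual"`.
#' @param onset_s Onset of the first stimulus in each trial, strictly
#'   increasing.
#' @param n_stimuli Number of stimuli in the trial (default 1).
#' @param stim_param Free-form annotation string (default `""`).
#' @return A tibble of class `trial_table`.
#' @export
trial_table <- function(trial_id = integer(), modality = character(),
                        onset_s = numeric(), n_stimuli = 1L, stim_param = "") {
  tt <- tibble(
    trial_id = as.integer(trial_id),
    modality = as.character(modality),
    onset_s = as.double(onset_s),
    n_stimuli = rep_len(as.integer(n_stimuli), length(trial_id)),
    stim_param = rep_len(as.character(stim_param), length(trial_id))
  )
  validate_trial_table(tt)
}

validate_trial_table <- function(tt) {
  if (nrow(tt) > 0) {
    if (!all(tt$modality %in% c("tactile", "visual"))) {
      abort("modality must be 'tactile' or 'visual'.")
    }
    if (is.unsorted(tt$onset_s, strictly = TRUE)) {
      abort("onset_s must be strictly increasing.")
    }
  }
  class(tt) <- c("trial_table", class(tibble()))
  tt
}

#' Sorted spike table
#'
#' Spike times of curated units (clusters) with the depth each cluster was
#' localised to. Spike sorting itself is upstream of this package; the table
#' is an input.
#'
#' @param cluster_id Integer cluster ids.
#' @param spike_time_s Spike times in seconds, nonnegative.
#' @param cluster_depth_um Depth of the cluster in micrometres.
#' @return A tibble of class `spike_table`, sorted by cluster then time.
#' @export
spike_table <- function(cluster_id = integer(), spike_time_s = numeric(),
                        cluster_depth_um = numeric()) {
  st <- tibble(
    cluster_id = as.integer(cluster_id),
    spike_time_s = as.double(spike_time_s),
    cluster_depth_um = rep_len(as.double(cluster_depth_um), length(cluster_id))
  )
  validate_spike_table(st)
}

validate_spike_table <- function(st) {
  if (nrow(st) > 0) {
    if (any(st$spike_time_s < 0)) abort("spike times must be nonnegative.")
    if (any(!is.finite(st$cluster_depth_um))) {
      abort("cluster_depth_um must be finite.")
    }
    st <- dplyr::arrange(st, .data$cluster_id, .data$spike_time_s)
  }
  class(st) <- c("spike_table", class(tibble()))
  st
}
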