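# On-disk session layout:
#   meta.json  - sampling_rate_hz, n_channels, dtype "int16" (little-endian),
#                mv_per_bit scale, start_time_s, geometry array
#   lfp.bin    - frame-interleaved int16 (sample 0 of all channels, sample 1, ...)
#   trials.tsv - trial_id, modality, onset_s, n_stimuli, stim_param
#   spikes.tsv - cluster_id, spike_time_s, cluster_depth_um

#' Write a session directory
#'
#' Serialises a session (geometry, LFP, trials, spikes) to the flat-binary
#' layout described in the package vignette: a JSON sidecar, an int16
#' little-endian frame-interleaved `lfp.bin`, and tab-separated trial and
#' spike tables. LFP samples are quantised to int16 at `mv_per_bit`; output
#' bytes are deterministic for identical inputs.
#'
#' @param session_dir Directory to create/write into.
#' @param geometry A [channel_geometry()].
#' @param lfp A [laminar_lfp()] whose rows correspond 1:1 to `geometry` rows.
#' @param trials A [trial_table()].
#' @param spikes A [spike_table()].
#' @param mv_per_bit Quantisation scale in mV per int16 bit.
#' @return `session_dir`, invisibly.
#' @export
write_session <- function(session_dir, geometry, lfp, trials, spikes,
                          mv_per_bit = 0.00195) {
  geometry <- validate_channel_geometry(geometry)
  if (!inherits(lfp, "laminar_lfp")) abort("`lfp` must be a laminar_lfp.")
  trials <- validate_trial_table(trials)
  spikes <- validate_spike_table(spikes)
  if (nrow(lfp$values) != nrow(geometry)) {
    abort("LFP row count must match the number of geometry channels.")
  }
  if (any(!is.finite(lfp$values))) abort("refusing to write non-finite LFP values.")
  stopifnot_scalar_number(mv_per_bit, "mv_per_bit", positive = TRUE)

  dir.create(session_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(session_dir)) abort(paste0("cannot create ", session_dir))

  ints <- round(lfp$values / mv_per_bit)
  if (any(abs(ints) > 32767)) {
    abort("LFP values exceed the int16 range at this mv_per_bit scale.")
  }
  # frame-interleaved: column-major write of the (channels x samples) matrix
  con <- file(file.path(session_dir, "lfp.bin"), "wb")
  writeBin(as.integer(ints), con, size = 2L, endian = "little")
  close(con)

  meta <- list(
    sampling_rate_hz = lfp$sampling_rate_hz,
    n_channels = nrow(geometry),
    n_samples = ncol(lfp$values),
    dtype = "int16",
    byte_order = "little",
    mv_per_bit = mv_per_bit,
    start_time_s = lfp$start_time_s,
    geometry = geometry[, c("channel_index", "depth_um", "lateral_um", "included")]
  )
  jsonlite::write_json(meta, file.path(session_dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_tsv(as_tibble(trials), file.path(session_dir, "trials.tsv"),
                   progress = FALSE)
  readr::write_tsv(as_tibble(spikes), file.path(session_dir, "spikes.tsv"),
                   progress = FALSE)
  invisible(session_dir)
}

#' Read a session directory
#'
#' Reads the layout written by [write_session()], validating the sidecar
#' against the binary payload (declared channel x sample count must match the
#' file size) and converting int16 samples to millivolts via the declared
#' scale. Missing trial or spike files yield empty tables with a warning.
#'
#' @param session_dir Directory containing `meta.json`, `lfp.bin`,
#'   `trials.tsv`, `spikes.tsv`.
#' @return A list with elements `geometry`, `lfp`, `trials`, `spikes`.
#' @export
read_session <- function(session_dir) {
  meta_path <- file.path(session_dir, "meta.json")
  bin_path <- file.path(session_dir, "lfp.bin")
  if (!file.exists(meta_path)) abort(paste0("missing sidecar: ", meta_path))
  if (!file.exists(bin_path)) abort(paste0("missing binary: ", bin_path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (f in c("sampling_rate_hz", "n_channels", "n_samples", "mv_per_bit")) {
    if (is.null(meta[[f]]) || !is.numeric(meta[[f]])) {
      abort(paste0("sidecar field missing or invalid: ", f))
    }
  }
  n_ch <- as.integer(meta$n_channels)
  n_samp <- as.integer(meta$n_samples)
  expect_bytes <- as.double(n_ch) * n_samp * 2
  actual_bytes <- file.info(bin_path)$size
  if (!isTRUE(actual_bytes == expect_bytes)) {
    abort(sprintf(
      "sidecar channel count x sample count (%d x %d = %.0f bytes) does not match lfp.bin size (%.0f bytes); check 'n_channels'/'n_samples'",
      n_ch, n_samp, expect_bytes, actual_bytes))
  }
  geom <- as_tibble(meta$geometry)
  geom <- channel_geometry(geom$channel_index, geom$depth_um, geom$lateral_um,
                           geom$included)
  con <- file(bin_path, "rb")
  ints <- readBin(con, integer(), n = n_ch * n_samp, size = 2L,
                  signed = TRUE, endian = "little")
  close(con)
  values <- matrix(ints * meta$mv_per_bit, nrow = n_ch)
  lfp <- laminar_lfp(values, meta$sampling_rate_hz, geom$depth_um,
                     meta$start_time_s %||% 0)

  trials_path <- file.path(session_dir, "trials.tsv")
  if (file.exists(trials_path)) {
    tr <- readr::read_tsv(trials_path, show_col_types = FALSE, progress = FALSE)
    trials <- trial_table(tr$trial_id, tr$modality, tr$onset_s,
                          tr$n_stimuli, tr$stim_param)
  } else {
    warn("trials.tsv not found; returning an empty trial table.")
    trials <- trial_table()
  }
  spikes_path <- file.path(session_dir, "spikes.tsv")
  if (file.exists(spikes_path)) {
    sp <- readr::read_tsv(spikes_path, show_col_types = FALSE, progress = FALSE)
    spikes <- spike_table(sp$cluster_id, sp$spike_time_s, sp$cluster_depth_um)
  } else {
    warn("spikes.tsv not found; returning an empty spike table.")
    spikes <- spike_table()
  }
  list(geometry = geom, lfp = lfp, trials = trials, spikes = spikes)
}
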