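# Peristimulus time histograms with baseline subtraction and cortical-layer
# assignment by depth.

#' Peristimulus time histogram
#'
#' Bins spike times relative to trial onsets (10-ms bins by default),
#' converts counts to firing rate (`count / (n_trials * bin_s)` in
#' spikes/s), and subtracts the mean rate over the baseline window (2 to 1 s
#' before onset by default). The unsubtracted rate is retained in
#' `raw_rate_hz` so that count conservation can be verified.
#'
#' @param spikes A [spike_table()] (or any data frame with `spike_time_s`);
#'   treated as one unit -- pass a single cluster, or pre-pooled spikes.
#' @param trials A [trial_table()] of surviving trials.
#' @param window_s `c(pre, post)` analysis window relative to onset.
#' @param bin_s Bin width in seconds (default 0.010).
#' @param baseline_window_s Baseline window relative to onset, default
#'   `c(-2, -1)`.
#' @return A tibble of class `peth`: `bin_start_s`, `bin_end_s`, `rate_hz`
#'   (baseline-subtracted), `raw_rate_hz`; attributes `n_trials`,
#'   `baseline_rate_hz`, `bin_s`.
#' @export
compute_peth <- function(spikes, trials, window_s = c(-0.1, 0.5),
                         bin_s = 0.010, baseline_window_s = c(-2, -1)) {
  if (nrow(trials) == 0L) abort("no trials for PETH computation.")
  stopifnot_scalar_number(bin_s, "bin_s", positive = TRUE)
  n_bins <- round((window_s[2] - window_s[1]) / bin_s)
  edges <- window_s[1] + bin_s * (0:n_bins)
  counts <- numeric(n_bins)
  n_base <- 0
  base_len <- baseline_window_s[2] - baseline_window_s[1]
  st <- spikes$spike_time_s
  for (on in trials$onset_s) {
    rel <- st - on
    in_win <- rel >= edges[1] & rel < edges[n_bins + 1L]
    if (any(in_win)) {
      b <- floor((rel[in_win] - window_s[1]) / bin_s) + 1L
      b[b > n_bins] <- n_bins
      tb <- tabulate(b, nbins = n_bins)
      counts <- counts + tb
    }
    n_base <- n_base + sum(rel >= baseline_window_s[1] &
                           rel < baseline_window_s[2])
  }
  n_tr <- nrow(trials)
  raw_rate <- counts / (n_tr * bin_s)
  base_rate <- n_base / (n_tr * base_len)
  out <- tibble(
    bin_start_s = edges[seq_len(n_bins)],
    bin_end_s = edges[-1L],
    rate_hz = raw_rate - base_rate,
    raw_rate_hz = raw_rate
  )
  structure(out, class = c("peth", class(tibble())),
            n_trials = n_tr, baseline_rate_hz = base_rate, bin_s = bin_s)
}

#' Assign a cortical layer from depth
#'
#' Maps a depth below the pia to `supragranular` (< 350 um, covering layers
#' II/III at 100-300 um), `granular` (350-500 um, around the thalamorecipient
#' layer IV at ~400 um), or `infragranular` (>= 500 um, layer V at
#' 500-900 um). Boundaries are exposed because anatomical reports give
#' ranges, not cutpoints.
#'
#' @param depth_um Depth(s) in micrometres, >= 0.
#' @param boundaries_um `c(granular_top, granular_bottom)` in micrometres
#'   (default `c(350, 500)`).
#' @return Character vector of layer labels.
#' @export
assign_layer <- function(depth_um, boundaries_um = c(350, 500)) {
  if (any(depth_um < 0)) abort("depth must be nonnegative.")
  ifelse(depth_um < boundaries_um[1], "supragranular",
         ifelse(depth_um < boundaries_um[2], "granular", "infragranular"))
}

#' Population PETHs by cortical layer
#'
#' Groups clusters by [assign_layer()] of their depth, computes each
#' cluster's baseline-subtracted PETH, and averages PETHs across the
#' clusters of a layer (unweighted: each cluster one vote). Layers with no
#' clusters are omitted with a warning.
#'
#' @param spikes A [spike_table()] with `cluster_id`, `cluster_depth_um`.
#' @param trials A [trial_table()].
#' @param window_s,bin_s,baseline_window_s As [compute_peth()].
#' @param boundaries_um Layer boundaries, see [assign_layer()].
#' @return A tibble: `layer`, `bin_start_s`, `bin_end_s`, `rate_hz`,
#'   `raw_rate_hz`, `n_clusters`.
#' @export
population_peth_by_layer <- function(spikes, trials, window_s = c(-0.1, 0.5),
                                     bin_s = 0.010,
                                     baseline_window_s = c(-2, -1),
                                     boundaries_um = c(350, 500)) {
  clusters <- dplyr::distinct(as_tibble(spikes)[, c("cluster_id", "cluster_depth_um")])
  clusters$layer <- assign_layer(clusters$cluster_depth_um, boundaries_um)
  layers <- c("supragranular", "granular", "infragranular")
  missing_layers <- setdiff(layers, unique(clusters$layer))
  if (length(missing_layers) > 0) {
    warn(paste0("no clusters in layer(s): ",
                paste(missing_layers, collapse = ", ")))
  }
  out <- list()
  for (lay in intersect(layers, unique(clusters$layer))) {
    ids <- clusters$cluster_id[clusters$layer == lay]
    peths <- lapply(ids, function(id) {
      compute_peth(spikes[spikes$cluster_id == id, , drop = FALSE], trials,
                   window_s, bin_s, baseline_window_s)
    })
    avg <- peths[[1]]
    if (length(peths) > 1) {
      avg$rate_hz <- rowMeans(vapply(peths, `[[`, numeric(nrow(avg)), "rate_hz"))
      avg$raw_rate_hz <- rowMeans(vapply(peths, `[[`, numeric(nrow(avg)),
                                         "raw_rate_hz"))
    }
    out[[lay]] <- tibble(layer = lay, avg[, c("bin_start_s", "bin_end_s",
                                              "rate_hz", "raw_rate_hz")],
                         n_clusters = length(ids))
  }
  dplyr::bind_rows(out)
}
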