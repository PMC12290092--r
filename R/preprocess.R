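# Artifact exclusion and baseline-corrected trial averaging. Detected
# epileptiform events poison nearby data too, so every event is padded by
# 15 s on both sides and all analyses skip the padded intervals.

#' Build an exclusion mask from event intervals
#'
#' Expands each event by `pad_s` on both sides (15 s by default), merges
#' overlapping expansions and clips to the recording bounds.
#'
#' @param events A data frame with `start_s`, `end_s` (disjoint intervals),
#'   e.g. from [detect_session_events()].
#' @param pad_s Padding in seconds on each side (default 15).
#' @param bounds Length-2 recording bounds `(t0, t1)` in seconds.
#' @return A tibble of class `exclusion_mask` with disjoint, sorted
#'   `start_s`, `end_s`.
#' @export
exclusion_mask_from_events <- function(events, pad_s = 15.0,
                                       bounds = c(-Inf, Inf)) {
  if (pad_s < 0) abort("pad_s must be nonnegative.")
  if (is.null(events) || nrow(events) == 0L) {
    m <- tibble(start_s = numeric(0), end_s = numeric(0))
  } else {
    m <- merge_intervals(pmax(events$start_s - pad_s, bounds[1]),
                         pmin(events$end_s + pad_s, bounds[2]))
  }
  structure(m, class = c("exclusion_mask", class(tibble())),
            bounds = as.double(bounds))
}

#' Drop trials overlapping excluded intervals
#'
#' Removes trials whose analysis window `[onset + pre, onset + post]`
#' overlaps any excluded interval.
#'
#' @param trials A [trial_table()].
#' @param mask An [exclusion_mask_from_events()] result.
#' @param analysis_window_s `c(pre, post)` relative to onset, `pre <= 0 <=
#'   post`.
#' @return The filtered trial table.
#' @export
filter_trials <- function(trials, mask, analysis_window_s = c(-2, 1)) {
  if (analysis_window_s[1] > 0 || analysis_window_s[2] < 0) {
    abort("analysis window must satisfy pre <= 0 <= post.")
  }
  if (is.null(mask) || nrow(mask) == 0L) return(trials)
  hit <- ranges_overlap_any(trials$onset_s + analysis_window_s[1],
                            trials$onset_s + analysis_window_s[2],
                            mask$start_s, mask$end_s)
  if (any(hit)) {
    inform(sprintf("filter_trials: removed %d of %d trials overlapping excluded intervals.",
                   sum(hit), nrow(trials)))
  }
  trials[!hit, , drop = FALSE]
}

#' Baseline-corrected trial-averaged LFP
#'
#' Aligns the LFP to each trial onset, subtracts that trial's mean over the
#' baseline window (per depth row), and averages across trials. The default
#' baseline window is 2 to 1 s before the first stimulus of the trial.
#'
#' @param lfp A per-depth-row [laminar_lfp()].
#' @param trials A [trial_table()] of surviving trials.
#' @param window_s `c(pre, post)` analysis window relative to onset.
#' @param baseline_window_s Baseline window relative to onset, default
#'   `c(-2, -1)`.
#' @return A [depth_time_profile()] in mV with trial-relative time.
#' @export
trial_average <- function(lfp, trials, window_s = c(-0.1, 0.4),
                          baseline_window_s = c(-2, -1)) {
  if (nrow(trials) == 0L) abort("no surviving trials to average.")
  fs <- lfp$sampling_rate_hz
  n <- ncol(lfp$values)
  rel_idx <- round(window_s[1] * fs):round(window_s[2] * fs)
  base_idx <- round(baseline_window_s[1] * fs):round(baseline_window_s[2] * fs)
  acc <- matrix(0, nrow(lfp$values), length(rel_idx))
  for (t in seq_len(nrow(trials))) {
    on_i <- round((trials$onset_s[t] - lfp$start_time_s) * fs) + 1L
    wi <- on_i + rel_idx
    bi <- on_i + base_idx
    if (min(wi, bi) < 1L || max(wi, bi) > n) {
      abort(sprintf("trial %d window extends outside the recording.",
                    trials$trial_id[t]))
    }
    snip <- lfp$values[, wi, drop = FALSE]
    base <- rowMeans(lfp$values[, bi, drop = FALSE])
    acc <- acc + (snip - base)
  }
  depth_time_profile(lfp$depth_um, rel_idx / fs, acc / nrow(trials),
                     units = "mV")
}
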