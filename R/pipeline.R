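# End-to-end orchestration. Stage order is fixed by the exclusion logic:
# epileptiform events are detected first, the padded exclusion mask is built,
# and only then are trials filtered and CSD / PSD / PETH computed, so that
# no analysis window overlaps an event or its 15-s surroundings. Group
# comparison of per-session scalars (CSD peak amplitude and time, gamma
# power, stimulus-induced PSD change) uses the rank-sum test.

#' Pipeline parameters
#'
#' All stage parameters with their reference defaults: conductivity
#' 0.3 S/m, disc radius 500 um, CSD depth smoothing SD 0.1 mm, STFT 2-s
#' Hamming window with 0.1-s step, detector band 0.5-10 Hz with z > 2
#' sustained >= 10 s at 500 um depth, 15-s exclusion padding, 10-ms PETH
#' bins, baseline window -2 to -1 s before onset, gamma band 30-120 Hz.
#' Unknown parameter names are an error (silent typos in scientific configs
#' are dangerous).
#'
#' @param ... Name-value overrides of the defaults listed above.
#' @return A list of class `pipeline_params`.
#' @export
pipeline_params <- function(...) {
  defaults <- list(
    sigma_S_per_m = 0.3,
    disk_radius_um = 500,
    smooth_sd_mm = 0.1,
    stft_window_s = 2.0,
    stft_step_s = 0.1,
    detect_band_hz = c(0.5, 10),
    detect_z = 2.0,
    detect_min_duration_s = 10.0,
    detect_depth_um = 500,
    exclusion_pad_s = 15.0,
    reject_channels = TRUE,
    mad_k = 5.0,
    csd_window_s = c(-0.1, 0.4),
    csd_baseline_window_s = c(-2, -1),
    csd_peak_depth_um = 400,
    csd_peak_window_s = c(0, 0.2),
    gamma_band_hz = c(30, 120),
    psd_depth_range_um = NULL,
    psd_freq_range_hz = NULL,
    psd_min_duration_s = 10,
    stim_window_s = c(0, 5),
    base_window_s = c(-2, -1),
    peth_window_s = c(-0.1, 0.5),
    peth_bin_s = 0.010,
    peth_baseline_window_s = c(-2, -1),
    layer_boundaries_um = c(350, 500),
    write_csd_profile = TRUE
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown pipeline parameter(s): ",
                 paste(unknown, collapse = ", ")))
  }
  p <- modifyList(defaults, overrides, keep.null = TRUE)
  structure(p, class = "pipeline_params")
}

#' Analyse one laminar session
#'
#' Runs the full per-session chain: channel rejection and same-depth
#' averaging (when the input is per-channel), epileptiform detection,
#' exclusion, trial filtering, baseline-corrected trial averaging, spline
#' iCSD with depth smoothing and peak extraction, depth-resolved PSD with
#' gamma band power, stimulus-induced PSD change, and layer-wise population
#' PETHs.
#'
#' @param session A `sim_session`, a session directory path, or a list with
#'   `geometry`, `lfp`, `trials`, `spikes`.
#' @param params A [pipeline_params()].
#' @return A list: `metrics` (tibble metric/value), `events`, `mask`,
#'   `csd_peak`, `csd` (smoothed profile), `psd`, `psd_change`, `peth`.
#' @export
analyze_session <- function(session, params = pipeline_params()) {
  if (is.character(session)) session <- read_session(session)
  geom <- session$geometry
  lfp <- session$lfp
  per_channel <- anyDuplicated(geom$depth_um) > 0 || !all(geom$included)
  if (per_channel && isTRUE(params$reject_channels)) {
    geom <- reject_channels(lfp, geom, mad_k = params$mad_k)
  }
  lfp <- average_same_depth(lfp, geom)

  events <- detect_session_events(
    lfp, target_depth_um = min(params$detect_depth_um, max(lfp$depth_um)),
    band_hz = params$detect_band_hz, window_s = params$stft_window_s,
    step_s = params$stft_step_s, z_threshold = params$detect_z,
    min_duration_s = params$detect_min_duration_s)
  t0 <- lfp$start_time_s
  t1 <- t0 + lfp_duration(lfp)
  mask <- exclusion_mask_from_events(events, pad_s = params$exclusion_pad_s,
                                     bounds = c(t0, t1))

  trials <- session$trials
  # drop trials whose analysis windows would leave the recording
  full_pre <- min(params$csd_baseline_window_s[1], params$base_window_s[1],
                  params$peth_baseline_window_s[1])
  full_post <- max(params$csd_window_s[2], params$stim_window_s[2],
                   params$peth_window_s[2])
  in_rec <- trials$onset_s + full_pre >= t0 & trials$onset_s + full_post <= t1
  trials <- trials[in_rec, , drop = FALSE]
  trials <- filter_trials(trials, mask, c(full_pre, full_post))
  tact <- trials[trials$modality == "tactile", , drop = FALSE]
  vis <- trials[trials$modality == "visual", , drop = FALSE]

  # CSD from tactile trial-averaged LFP
  csd_peak <- NULL; csd_sm <- NULL
  if (nrow(tact) > 0) {
    avg <- trial_average(lfp, tact, params$csd_window_s,
                         params$csd_baseline_window_s)
    csd <- estimate_csd(avg, csd_config(params$sigma_S_per_m,
                                        params$disk_radius_um,
                                        params$smooth_sd_mm))
    csd_sm <- smooth_csd_depth(csd, params$smooth_sd_mm)
    csd_peak <- extract_peak_response(csd_sm, params$csd_peak_depth_um,
                                      params$csd_peak_window_s)
  }

  # spectral read-outs, optionally restricted to a depth range of interest
  lfp_psd <- lfp
  if (!is.null(params$psd_depth_range_um)) {
    rows <- which(lfp$depth_um >= params$psd_depth_range_um[1] &
                  lfp$depth_um <= params$psd_depth_range_um[2])
    if (length(rows) == 0L) abort("psd_depth_range_um selects no depth rows.")
    lfp_psd <- laminar_lfp(lfp$values[rows, , drop = FALSE],
                           lfp$sampling_rate_hz, lfp$depth_um[rows],
                           lfp$start_time_s)
  }
  psd <- depth_psd(lfp_psd, mask, params$stft_window_s, params$stft_step_s,
                   params$psd_freq_range_hz, params$psd_min_duration_s)
  gamma_db <- band_power(psd, params$gamma_band_hz, params$psd_depth_range_um)

  change <- NULL; change_pct <- NA_real_
  if (nrow(vis) > 0) {
    change <- stimulus_psd_change(lfp_psd, vis, params$stim_window_s,
                                  params$base_window_s,
                                  params$stft_window_s, params$stft_step_s,
                                  params$psd_freq_range_hz)
    change_pct <- psd_change_summary(change, params$gamma_band_hz,
                                     params$psd_depth_range_um)
  }

  peth <- NULL
  if (nrow(session$spikes) > 0 && nrow(tact) > 0) {
    peth <- population_peth_by_layer(session$spikes, tact,
                                     params$peth_window_s, params$peth_bin_s,
                                     params$peth_baseline_window_s,
                                     params$layer_boundaries_um)
  }

  metrics <- tibble(
    metric = c("csd_peak_amplitude_uA_mm3", "csd_peak_time_ms",
               "gamma_power_dbmv", "stim_psd_change_pct"),
    value = c(csd_peak$peak_amplitude_uA_mm3 %||% NA_real_,
              csd_peak$peak_time_ms %||% NA_real_,
              gamma_db, change_pct)
  )
  list(metrics = metrics, events = events, mask = mask, csd_peak = csd_peak,
       csd = csd_sm, psd = psd, psd_change = change, peth = peth,
       n_trials_used = c(tactile = nrow(tact), visual = nrow(vis)))
}

write_session_outputs <- function(res, dir, write_csd_profile = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(res$events, file.path(dir, "events.tsv"), progress = FALSE)
  readr::write_tsv(as_tibble(res$mask), file.path(dir, "excluded.tsv"),
                   progress = FALSE)
  if (!is.null(res$csd_peak)) {
    readr::write_tsv(res$csd_peak, file.path(dir, "csd_peaks.tsv"),
                     progress = FALSE)
  }
  if (!is.null(res$csd) && write_csd_profile) {
    prof <- tidy(res$csd)
    prof$time_ms <- prof$time_s * 1000
    readr::write_tsv(prof[, c("depth_um", "time_ms", "value")],
                     file.path(dir, "csd_profile.tsv"), progress = FALSE)
  }
  readr::write_tsv(tidy(res$psd), file.path(dir, "depth_psd.tsv"),
                   progress = FALSE)
  if (!is.null(res$psd_change)) {
    readr::write_tsv(tidy(res$psd_change), file.path(dir, "psd_change.tsv"),
                     progress = FALSE)
  }
  if (!is.null(res$peth)) {
    peth <- res$peth
    peth$bin_start_ms <- peth$bin_start_s * 1000
    readr::write_tsv(peth[, c("layer", "bin_start_ms", "rate_hz",
                              "raw_rate_hz", "n_clusters")],
                     file.path(dir, "peth.tsv"), progress = FALSE)
  }
  invisible(dir)
}

#' Run the full two-group pipeline
#'
#' For every session: detect epileptiform events, build the exclusion mask,
#' and compute the CSD, spectral and spiking read-outs; then compare the
#' per-session scalars between the two groups with the rank-sum test. All
#' tabular outputs are written as TSV under `out_dir`; re-running with an
#' identical session set and parameters reproduces the outputs byte for
#' byte.
#'
#' @param sessions A tibble with columns `group`, `session_id`, and either
#'   `session` (list-column of session objects, e.g. from
#'   [simulate_cohort()]) or `path` (session directories). Exactly two
#'   distinct groups are required.
#' @param out_dir Output directory (created).
#' @param params A [pipeline_params()].
#' @return A list: `comparison` (tibble), `metrics` (per-session long
#'   tibble), `out_dir`. Written files: per session `events.tsv`,
#'   `excluded.tsv`, `csd_peaks.tsv`, `csd_profile.tsv`, `depth_psd.tsv`,
#'   `psd_change.tsv`, `peth.tsv`; per run `comparison.tsv`,
#'   `session_metrics.tsv`, `manifest.json`, `run.log`.
#' @export
run_pipeline <- function(sessions, out_dir, params = pipeline_params()) {
  if (!all(c("group", "session_id") %in% names(sessions))) {
    abort("`sessions` needs columns group, session_id and session or path.")
  }
  groups <- unique(sessions$group)
  if (length(groups) != 2L) abort("exactly two groups are required.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    inform(msg)
  }
  say("pipeline start: %d sessions in groups [%s]", nrow(sessions),
      paste(groups, collapse = ", "))
  for (nm in names(params)) {
    say("param %s = %s", nm, paste(format(params[[nm]]), collapse = ","))
  }

  all_metrics <- list()
  for (i in seq_len(nrow(sessions))) {
    sid <- sessions$session_id[i]
    src <- if ("session" %in% names(sessions)) sessions$session[[i]] else
      sessions$path[i]
    res <- tryCatch(
      analyze_session(src, params),
      error = function(e) {
        say("session %s FAILED: %s", sid, conditionMessage(e))
        NULL
      })
    if (is.null(res)) next
    write_session_outputs(res, file.path(out_dir, "sessions", sid),
                          params$write_csd_profile)
    say("session %s: %d events, %d/%d tactile/visual trials used", sid,
        nrow(res$events), res$n_trials_used[["tactile"]],
        res$n_trials_used[["visual"]])
    m <- res$metrics
    m$group <- sessions$group[i]
    m$session_id <- sid
    all_metrics[[sid]] <- m
  }
  metrics <- dplyr::bind_rows(all_metrics)
  if (nrow(metrics) == 0L) {
    abort("all sessions failed; groups ended with no analysable sessions.")
  }
  for (g in groups) {
    if (!any(metrics$group == g)) {
      abort(paste0("group '", g, "' ended with no analysable sessions."))
    }
  }

  comparison <- compare_groups(metrics, groups)
  readr::write_tsv(comparison, file.path(out_dir, "comparison.tsv"),
                   progress = FALSE)
  readr::write_tsv(metrics[, c("group", "session_id", "metric", "value")],
                   file.path(out_dir, "session_metrics.tsv"), progress = FALSE)
  manifest <- list(
    groups = as.list(table(sessions$group)),
    params = unclass(params),
    n_sessions = nrow(sessions),
    package_version = as.character(utils::packageVersion("laminarlfp")),
    r_version = R.version.string
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, log_path)
  list(comparison = comparison, metrics = metrics, out_dir = out_dir)
}

# Rank-sum comparison of each metric between the two groups; first group in
# `groups` is the reference (its rank-sum is the reported W).
compare_groups <- function(metrics, groups) {
  out <- list()
  for (met in unique(metrics$metric)) {
    x <- metrics$value[metrics$metric == met & metrics$group == groups[1]]
    y <- metrics$value[metrics$metric == met & metrics$group == groups[2]]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) == 0L || length(y) == 0L) next
    ts <- ranksum_test(x, y)
    s1 <- group_summary(x); s2 <- group_summary(y)
    out[[met]] <- tibble(
      metric = met,
      mean_1 = s1$mean, sem_1 = s1$sem, n_1 = s1$n,
      mean_2 = s2$mean, sem_2 = s2$sem, n_2 = s2$n,
      group_1 = groups[1], group_2 = groups[2],
      W = ts$statistic, p = ts$p_two_sided, method = ts$method
    )
  }
  dplyr::bind_rows(out)
}
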