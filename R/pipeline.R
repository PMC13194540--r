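#' End-to-end analysis pipelines
#'
#' `run_standard()` composes the full standard-wall analysis: load or take
#' simulated trials, impute dropouts, segment paw events, build the stride,
#' phase-sample and Jaccard tables, summarise each pair's circular
#' distribution per mouse and at the group level, and fit the group models.
#' `run_gapcross()` adds gap-relative location labels, outcome
#' classification, above-vs-at-gap circular contrasts and
#' location-effect Jaccard models.
#'
#' @name pipeline_cli
#' @keywords internal
NULL

#' Default analysis options
#'
#' @param enter_thresh,exit_thresh,min_event_s,window_frames event
#'   detection (see [detect_events()]).
#' @param slip_thresh slip threshold, cm/s.
#' @param max_gap_frames,conf_floor dropout imputation.
#' @param body_speed_window_s body-speed window.
#' @param liftoff_pct lift-off duration percentile filter.
#' @param bin_width_cm_s gait speed-bin width.
#' @param min_mice_per_bin bin-inclusion rule for inference.
#' @return named list of options.
#' @export
analysis_options <- function(enter_thresh = 2, exit_thresh = 1,
                             min_event_s = 0.025, window_frames = 13,
                             slip_thresh = -10, max_gap_frames = 10,
                             conf_floor = 0.5, body_speed_window_s = 0.5,
                             liftoff_pct = 90, bin_width_cm_s = 1.6,
                             min_mice_per_bin = 8) {
  as.list(environment())
}

#' Analyse one trial
#'
#' @param track a [pose_track()].
#' @param opts [analysis_options()].
#' @return list with `events`, `strides`, `phases`, `overlaps`,
#'   `trial_speed`, `slip_count`.
#' @export
analyze_trial <- function(track, opts = analysis_options()) {
  track <- impute_gaps(track, opts$max_gap_frames, opts$conf_floor)
  ## interpolate any remaining long dropouts so downstream maths stays
  ## finite; segments attribute records where the track was unreliable
  for (kp in KEYPOINTS) {
    c_ <- track$coords[[kp]]
    bad <- !is.finite(c_$x) | !is.finite(c_$y)
    if (any(bad)) {
      ok <- !bad
      c_$x[bad] <- approx(track$time_s[ok], c_$x[ok],
                          xout = track$time_s[bad], rule = 2)$y
      c_$y[bad] <- approx(track$time_s[ok], c_$y[ok],
                          xout = track$time_s[bad], rule = 2)$y
      track$coords[[kp]] <- c_
    }
  }
  events <- segment_track(track, opts$enter_thresh, opts$exit_thresh,
                          opts$min_event_s, opts$window_frames,
                          opts$slip_thresh)
  strides <- compute_stride_metrics(track, events)
  phases <- trial_phase_samples(events, track, opts$body_speed_window_s)
  overlaps <- trial_pair_overlaps(events, track$meta)
  ts <- trial_speed_20cm(track)
  list(events = events, strides = strides, phases = phases,
       overlaps = overlaps, trial_speed = ts,
       slip_count = sum(vapply(events, function(e) length(e$slip_times_s), 1L)),
       track = track)
}

## resolve input to a list of tracks (+ optional ground truth)
resolve_trials <- function(input, cal = calibration()) {
  if (is.list(input) && !is.null(input$trials)) {
    lapply(input$trials, function(tr) tr$track)
  } else if (is.character(input) && dir.exists(input)) {
    man <- read.csv(file.path(input, "manifest.csv"))
    lapply(seq_len(nrow(man)), function(i)
      load_trial(file.path(input, man$file[i]), cal,
                 meta = list(mouse_id = man$mouse_id[i],
                             session_id = man$session_id[i],
                             trial_id = man$trial_id[i],
                             wall_type = man$wall_type[i])))
  } else stop("run_standard(): input must be a simulate_cohort() result or a manifest directory")
}

#' Run the standard-wall analysis over a cohort
#'
#' @param input a [simulate_cohort()] result or a directory containing
#'   per-trial CSVs plus `manifest.csv`.
#' @param opts [analysis_options()].
#' @param out_dir optional output directory for tidy CSV tables and a text
#'   report.
#' @param cal calibration used when loading from files.
#' @return list with `stride_records`, `phase_samples` (lift-off filtered;
#'   the unfiltered set as `phase_samples_raw`), `pair_overlaps`,
#'   `circular_summaries` (per pair x mouse), `group_circular` (per pair),
#'   `gait_binned`, `trial_speeds`, `slips`, `jaccard_pair_model`,
#'   `n_failed` and `failed_trials`.
#' @export
run_standard <- function(input, opts = analysis_options(), out_dir = NULL,
                         cal = calibration()) {
  tracks <- resolve_trials(input, cal)
  if (!length(tracks)) stop("run_standard(): empty manifest")
  strides <- list(); phases <- list(); overlaps <- list()
  speeds <- list(); slips <- list(); failed <- character()
  for (tr in tracks) {
    res <- tryCatch(analyze_trial(tr, opts), error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, paste(tr$meta$mouse_id, tr$meta$session_id,
                                tr$meta$trial_id, conditionMessage(res),
                                sep = " | "))
      next
    }
    strides[[length(strides) + 1L]] <- res$strides
    phases[[length(phases) + 1L]] <- res$phases
    overlaps[[length(overlaps) + 1L]] <- res$overlaps
    speeds[[length(speeds) + 1L]] <- data.frame(
      mouse_id = tr$meta$mouse_id, session_id = tr$meta$session_id,
      trial_id = tr$meta$trial_id, speed_cm_s = res$trial_speed$speed_cm_s,
      excluded = res$trial_speed$excluded, stringsAsFactors = FALSE)
    slips[[length(slips) + 1L]] <- data.frame(
      mouse_id = tr$meta$mouse_id, session_id = tr$meta$session_id,
      trial_id = tr$meta$trial_id, n_slips = res$slip_count,
      stringsAsFactors = FALSE)
  }
  stride_records <- do.call(rbind, strides)
  phase_raw <- do.call(rbind, phases)
  pair_overlaps <- do.call(rbind, overlaps)
  trial_speeds <- do.call(rbind, speeds)
  slip_tab <- do.call(rbind, slips)
  ## lift-off filter is computed on the whole pooled group, per pair
  phase_filt <- do.call(rbind, lapply(split(phase_raw, phase_raw$pair),
                                      liftoff_percentile_filter,
                                      pct = opts$liftoff_pct))
  rownames(phase_filt) <- NULL
  circ_pm <- per_mouse_circular(phase_filt)
  group_circ <- group_circular(circ_pm)
  gait_binned <- bin_by_speed(stride_records, opts$bin_width_cm_s,
                              opts$min_mice_per_bin)
  jac_model <- tryCatch(
    lmm_fit(transform(pair_overlaps,
                      pair = factor(pair, levels = names(PAIR_DEFS))),
            "jaccard", "pair"),
    error = function(e) NULL)
  out <- list(stride_records = stride_records,
              phase_samples = phase_filt, phase_samples_raw = phase_raw,
              pair_overlaps = pair_overlaps,
              circular_summaries = circ_pm, group_circular = group_circ,
              gait_binned = gait_binned, trial_speeds = trial_speeds,
              slips = slip_tab, jaccard_pair_model = jac_model,
              n_failed = length(failed), failed_trials = failed,
              opts = opts)
  if (!is.null(out_dir)) write_results(out, out_dir)
  out
}

per_mouse_circular <- function(samples) {
  if (is.null(samples) || !nrow(samples)) return(NULL)
  sp <- split(samples, list(samples$pair, samples$mouse_id,
                            samples$location), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(sub) {
    s <- circ_mean(sub$phi_deg)
    data.frame(pair = sub$pair[1], mouse_id = sub$mouse_id[1],
               location = sub$location[1], n = s$n,
               mean_deg = s$mean_direction_deg, r = s$resultant_r,
               circ_sd_deg = s$circ_sd_deg, rayleigh_z = s$rayleigh_z,
               rayleigh_p = s$rayleigh_p, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

group_circular <- function(circ_pm) {
  if (is.null(circ_pm) || !nrow(circ_pm)) return(NULL)
  sp <- split(circ_pm, list(circ_pm$pair, circ_pm$location), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(sub) {
    s <- circ_mean(sub$mean_deg)
    data.frame(pair = sub$pair[1], location = sub$location[1],
               n_mice = nrow(sub), mean_deg = s$mean_direction_deg,
               circ_sd_deg = s$circ_sd_deg, r = s$resultant_r,
               rayleigh_p = s$rayleigh_p,
               mean_mouse_r = mean(sub$r), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Run the gap-wall analysis over a cohort
#'
#' Standard pipeline plus gap-relative location labels on phase samples,
#' strides and Jaccard overlaps, outcome classification and session
#' summaries, above-vs-at-gap Watson-Williams contrasts per pair (p values
#' Bonferroni-adjusted across the pairs tested) and per-limb-class Jaccard
#' location models.
#'
#' @inheritParams run_standard
#' @param gap a [gap_spec()].
#' @param pad band padding (cm) for the location labels.
#' @return the [run_standard()] bundle extended with `outcomes`,
#'   `gap_summary`, `location_contrasts` and `jaccard_location_models`;
#'   the phase and overlap tables carry gap locations.
#' @export
run_gapcross <- function(input, gap, opts = analysis_options(),
                         out_dir = NULL, cal = calibration(), pad = 0) {
  tracks <- resolve_trials(input, cal)
  if (!length(tracks)) stop("run_gapcross(): empty manifest")
  strides <- list(); phases <- list(); overlaps <- list()
  outcomes <- list(); failed <- character()
  for (tr in tracks) {
    res <- tryCatch(analyze_trial(tr, opts), error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, paste(tr$meta$mouse_id, tr$meta$trial_id,
                                conditionMessage(res), sep = " | "))
      next
    }
    ph <- label_sample_location(res$phases, res$events, res$track, gap, pad)
    st <- label_stride_location(res$strides, res$events, res$track, gap, pad)
    ## a trial's overlaps split by gap location: recompute the Jaccard on
    ## reaches wholly above vs reaches spanning the band
    ov <- gap_split_overlaps(res$events, res$track, gap, tr$meta, pad)
    strides[[length(strides) + 1L]] <- st
    phases[[length(phases) + 1L]] <- ph
    overlaps[[length(overlaps) + 1L]] <- ov
    outcomes[[length(outcomes) + 1L]] <- classify_cross(res$track, gap)
  }
  stride_records <- do.call(rbind, strides)
  phase_raw <- do.call(rbind, phases)
  pair_overlaps <- do.call(rbind, overlaps)
  outcome_tab <- do.call(rbind, outcomes)
  phase_raw <- phase_raw[!is.na(phase_raw$location), , drop = FALSE]
  phase_filt <- do.call(rbind, lapply(split(phase_raw, phase_raw$pair),
                                      liftoff_percentile_filter,
                                      pct = opts$liftoff_pct))
  rownames(phase_filt) <- NULL
  circ_pm <- per_mouse_circular(phase_filt)
  group_circ <- group_circular(circ_pm)
  loc_con <- location_contrasts(circ_pm)
  jac_models <- jaccard_location_models(pair_overlaps)
  out <- list(stride_records = stride_records, phase_samples = phase_filt,
              phase_samples_raw = phase_raw, pair_overlaps = pair_overlaps,
              circular_summaries = circ_pm, group_circular = group_circ,
              outcomes = outcome_tab,
              gap_summary = gap_session_summary(outcome_tab),
              location_contrasts = loc_con,
              jaccard_location_models = jac_models,
              n_failed = length(failed), failed_trials = failed,
              opts = opts, gap = gap)
  if (!is.null(out_dir)) write_results(out, out_dir)
  out
}

## per-trial Jaccard computed separately on above-gap reaches and on
## band-spanning reaches of each pair
gap_split_overlaps <- function(events, track, gap, meta, pad = 0) {
  t <- track$time_s
  reach_loc <- function(paw) {
    iv <- events[[paw]]$reach_intervals
    if (!nrow(iv)) return(cbind(iv, loc = character(0)))
    y <- kp_xy(track, paw)$y
    ys <- interp_at(t, y, iv$start_s); ye <- interp_at(t, y, iv$end_s)
    loc <- ifelse(reach_spans_gap(ys, ye, gap, pad), "at_gap",
                  ifelse(pmin(ys, ye) > gap$gap_top_cm - pad, "above_gap",
                         NA_character_))
    iv$loc <- loc
    iv
  }
  locs <- lapply(PAWS, reach_loc); names(locs) <- PAWS
  rows <- list()
  for (p in names(PAIR_DEFS)) {
    ab <- PAIR_DEFS[[p]]
    for (L in c("above_gap", "at_gap")) {
      a <- locs[[ab[1]]]; b <- locs[[ab[2]]]
      a <- a[!is.na(a$loc) & a$loc == L, c("start_s", "end_s"), drop = FALSE]
      b <- b[!is.na(b$loc) & b$loc == L, c("start_s", "end_s"), drop = FALSE]
      if (!nrow(a) && !nrow(b)) next
      rows[[length(rows) + 1L]] <- data.frame(
        pair = p, jaccard = jaccard_index(a, b),
        mouse_id = meta$mouse_id %||% NA_character_,
        session_id = meta$session_id %||% NA_character_,
        trial_id = meta$trial_id %||% NA_character_,
        location = L, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

## Watson-Williams above vs at gap per pair on per-mouse circular means,
## Bonferroni across the pairs tested (one figure-panel family)
location_contrasts <- function(circ_pm) {
  if (is.null(circ_pm)) return(NULL)
  pairs <- unique(circ_pm$pair)
  rows <- list()
  for (p in pairs) {
    a <- circ_pm$mean_deg[circ_pm$pair == p & circ_pm$location == "above_gap"]
    b <- circ_pm$mean_deg[circ_pm$pair == p & circ_pm$location == "at_gap"]
    if (length(a) < 3 || length(b) < 3) next
    ww <- suppressWarnings(watson_williams(list(a, b)))
    rows[[length(rows) + 1L]] <- data.frame(
      pair = p, F = ww$F, p_raw = ww$p,
      mean_above_deg = circ_mean(a)$mean_direction_deg,
      mean_at_gap_deg = circ_mean(b)$mean_direction_deg,
      n_above = length(a), n_at_gap = length(b), stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(out$p_raw * nrow(out), 1)
  out
}

jaccard_location_models <- function(pair_overlaps) {
  if (is.null(pair_overlaps)) return(NULL)
  out <- list()
  for (p in c("FF", "HH")) {
    sub <- pair_overlaps[pair_overlaps$pair == p &
                           pair_overlaps$location %in% c("above_gap", "at_gap"), ]
    if (!nrow(sub)) next
    sub$location <- factor(sub$location, levels = c("at_gap", "above_gap"))
    out[[p]] <- tryCatch(suppressWarnings(lmm_fit(sub, "jaccard", "location")),
                         error = function(e) NULL)
  }
  out
}

## tidy CSV tables + a small text report
write_results <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wr <- function(x, f) if (!is.null(x) && is.data.frame(x) && nrow(x))
    write.csv(x, file.path(out_dir, f), row.names = FALSE)
  wr(res$stride_records, "stride_records.csv")
  wr(res$phase_samples, "phase_samples.csv")
  wr(res$pair_overlaps, "pair_overlaps.csv")
  wr(res$circular_summaries, "circular_summaries.csv")
  wr(res$group_circular, "group_circular.csv")
  wr(res$gait_binned, "gait_binned.csv")
  wr(res$trial_speeds, "trial_speeds.csv")
  wr(res$outcomes, "outcomes.csv")
  if (!is.null(res$jaccard_pair_model))
    wr(res$jaccard_pair_model$fixed_effects, "jaccard_pair_model.csv")
  meta <- list(package_version = as.character(utils::packageVersion("climbkit")),
               r_version = R.version.string,
               options = res$opts, n_failed = res$n_failed)
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  rpt <- file.path(out_dir, "report.txt")
  con <- file(rpt, "w"); on.exit(close(con))
  writeLines("climbkit analysis report", con)
  writeLines(sprintf("trials analysed, %d failed/skipped", res$n_failed), con)
  if (!is.null(res$group_circular)) {
    writeLines("", con)
    writeLines("Group circular summaries (per pair):", con)
    writeLines(utils::capture.output(print(res$group_circular, digits = 3)), con)
  }
  if (!is.null(res$location_contrasts)) {
    writeLines("", con)
    writeLines("Above-gap vs at-gap Watson-Williams contrasts:", con)
    writeLines(utils::capture.output(print(res$location_contrasts, digits = 3)), con)
  }
  invisible(rpt)
}
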