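#' Gap-crossing wall analysis
#'
#' The gap wall replaces a horizontal band of the climbing grid with a
#' smooth surface the paws cannot grip; the animal must reach across it.
#' These helpers locate coordination samples and strides relative to the
#' band, classify trial outcomes, and summarise success rates and crossing
#' times.
#'
#' @name gapcross
#' @keywords internal
NULL

#' Gap band geometry
#'
#' @param gap_bottom_cm y of the band bottom.
#' @param gap_height_cm band height (default 3.4 cm: the ungrippable
#'   section plus its grid spacing).
#' @param wall_height_cm wall height.
#' @return object of class `gap_spec`.
#' @export
gap_spec <- function(gap_bottom_cm = 18, gap_height_cm = 3.4,
                     wall_height_cm = 40) {
  stopifnot(gap_bottom_cm > 0,
            gap_bottom_cm + gap_height_cm < wall_height_cm)
  structure(list(gap_bottom_cm = gap_bottom_cm,
                 gap_height_cm = gap_height_cm,
                 gap_top_cm = gap_bottom_cm + gap_height_cm,
                 wall_height_cm = wall_height_cm),
            class = "gap_spec")
}

## does a reach that starts at y0 and grasps at y1 span the gap band?
reach_spans_gap <- function(y_start, y_end, gap, pad = 0) {
  y_start < gap$gap_top_cm + pad & y_end > gap$gap_bottom_cm - pad &
    y_end > y_start
}

#' Label phase samples relative to the gap band
#'
#' A sample is `at_gap` when any reach interval of either paw overlapping
#' its reference period spans the gap band (starts below the band top and
#' grasps above the band bottom); `above_gap` when all contributing events
#' sit wholly above the band top; samples wholly below the band are
#' excluded (location `NA`).
#'
#' @param samples phase-sample table (see [trial_phase_samples()]).
#' @param events per-paw [limb_events()] of the same trial.
#' @param track the trial's [pose_track()].
#' @param gap a [gap_spec()].
#' @param pad band padding in cm for the spanning test.
#' @return `samples` with `location` filled in (`"at_gap"`, `"above_gap"`
#'   or `NA` for excluded).
#' @export
label_sample_location <- function(samples, events, track, gap, pad = 0) {
  if (!inherits(gap, "gap_spec")) stop("label_sample_location(): need a gap_spec")
  if (!nrow(samples)) return(samples)
  t <- track$time_s
  ## per paw: reach interval bounds and the paw's y at those times
  info <- lapply(PAWS, function(p) {
    iv <- events[[p]]$reach_intervals
    y <- kp_xy(track, p)$y
    list(rs = iv$start_s, re = iv$end_s,
         ys = interp_at(t, y, iv$start_s), ye = interp_at(t, y, iv$end_s))
  })
  names(info) <- PAWS
  loc <- rep(NA_character_, nrow(samples))
  for (i in seq_len(nrow(samples))) {
    t0 <- samples$t0_s[i]; t1 <- samples$t1_s[i]
    span <- FALSE; all_above <- TRUE; any_ev <- FALSE
    for (p in c(samples$reference_paw[i], samples$target_paw[i])) {
      pi <- info[[p]]
      k <- pi$re > t0 & pi$rs < t1
      if (!any(k)) next
      any_ev <- TRUE
      span <- span || any(reach_spans_gap(pi$ys[k], pi$ye[k], gap, pad))
      all_above <- all_above &&
        all(pmin(pi$ys[k], pi$ye[k]) > gap$gap_top_cm - pad)
    }
    loc[i] <- if (span) "at_gap"
      else if (any_ev && all_above) "above_gap" else NA_character_
  }
  samples$location <- loc
  samples
}

#' Label stride records relative to the gap band
#'
#' A stride is `at_gap` when its reach spans the band, `above_gap` when it
#' lies wholly above the band top, excluded (`NA`) otherwise.
#'
#' @param records stride table from [compute_stride_metrics()].
#' @param track,gap,pad as in [label_sample_location()].
#' @param events per-paw [limb_events()].
#' @return `records` with `location` filled in.
#' @export
label_stride_location <- function(records, events, track, gap, pad = 0) {
  if (!nrow(records)) return(records)
  t <- track$time_s
  loc <- rep(NA_character_, nrow(records))
  for (i in seq_len(nrow(records))) {
    p <- records$paw[i]
    y <- kp_xy(track, p)$y
    ## the stride's reach: between its grasps
    ev <- events[[p]]
    r_in <- ev$reach_onsets_s[ev$reach_onsets_s > records$stride_start_s[i] &
                                ev$reach_onsets_s < records$stride_end_s[i]]
    if (length(r_in) != 1L) next
    ys <- interp_at(t, y, r_in); ye <- interp_at(t, y, records$stride_end_s[i])
    loc[i] <- if (reach_spans_gap(ys, ye, gap, pad)) "at_gap"
      else if (min(ys, ye) > gap$gap_top_cm - pad) "above_gap"
      else NA_character_
  }
  records$location <- loc
  records
}

#' Classify a gap-wall trial's crossing outcome
#'
#' `success`: nose and tail base both end above the band top (the whole
#' body clears the gap). `attempt`: the nose or a forepaw exceeds the band
#' bottom but the body never clears. `no_approach`: otherwise. For
#' successes, `time_to_cross_s` runs from the first nose crossing of the
#' band bottom to the first tail-base crossing of the band top.
#'
#' @param track a [pose_track()].
#' @param gap a [gap_spec()].
#' @return data.frame with `trial_id`, `mouse_id`, `session_id`, `outcome`,
#'   `time_to_cross_s`.
#' @export
classify_cross <- function(track, gap) {
  nose <- kp_xy(track, "nose"); tb <- kp_xy(track, "tail_base")
  if (all(!is.finite(nose$y))) stop("classify_cross(): nose track missing")
  t <- track$time_s
  fore_max <- max(c(kp_xy(track, "rf")$y, kp_xy(track, "lf")$y), na.rm = TRUE)
  nose_max <- max(nose$y, na.rm = TRUE)
  tb_max <- max(tb$y, na.rm = TRUE)
  cleared <- nose_max > gap$gap_top_cm && tb_max > gap$gap_top_cm
  reached <- nose_max > gap$gap_bottom_cm || fore_max > gap$gap_bottom_cm
  outcome <- if (cleared) "success" else if (reached) "attempt" else "no_approach"
  ttc <- NA_real_
  if (cleared) {
    i_nose <- which(nose$y > gap$gap_bottom_cm)[1]
    i_tb <- which(tb$y > gap$gap_top_cm)[1]
    if (!is.na(i_nose) && !is.na(i_tb) && t[i_tb] > t[i_nose])
      ttc <- t[i_tb] - t[i_nose]
  }
  data.frame(trial_id = track$meta$trial_id, mouse_id = track$meta$mouse_id,
             session_id = track$meta$session_id, outcome = outcome,
             time_to_cross_s = ttc, stringsAsFactors = FALSE)
}

#' Per-mouse, per-session gap-cross summary
#'
#' Success rate is successes over approaches (successes + attempts;
#' `no_approach` trials are not counted). Grand averages are mean +/- SD
#' across mice.
#'
#' @param outcomes data.frame of [classify_cross()] rows.
#' @return list with `per_mouse_session` (success_rate, mean time to cross,
#'   counts; rate is `NA`-flagged when a session has no approaches) and
#'   `grand` (per-session mean +/- SD across mice).
#' @export
gap_session_summary <- function(outcomes) {
  sp <- split(outcomes, list(outcomes$mouse_id, outcomes$session_id),
              drop = TRUE)
  pm <- do.call(rbind, lapply(sp, function(sub) {
    ns <- sum(sub$outcome == "success"); na_ <- sum(sub$outcome == "attempt")
    data.frame(mouse_id = sub$mouse_id[1], session_id = sub$session_id[1],
               n_success = ns, n_attempt = na_,
               success_rate = if (ns + na_ > 0) ns / (ns + na_) else NA_real_,
               mean_time_to_cross_s =
                 if (ns > 0) mean(sub$time_to_cross_s, na.rm = TRUE) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(pm) <- NULL
  grand <- do.call(rbind, lapply(split(pm, pm$session_id), function(sub) {
    data.frame(session_id = sub$session_id[1],
               success_rate_mean = mean(sub$success_rate, na.rm = TRUE),
               success_rate_sd = stats::sd(sub$success_rate, na.rm = TRUE),
               time_to_cross_mean = mean(sub$mean_time_to_cross_s, na.rm = TRUE),
               time_to_cross_sd = stats::sd(sub$mean_time_to_cross_s, na.rm = TRUE),
               n_mice = nrow(sub))
  }))
  rownames(grand) <- NULL
  list(per_mouse_session = pm, grand = grand)
}
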