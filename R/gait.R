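#' Per-stride gait metrics
#'
#' One record per stride (consecutive grasp pair of one paw) holding the
#' standard climbing gait variables: reach length (paw path length during
#' the reach), step length (vertical distance to the homologous paw at the
#' grasp), stride length (vertical distance between the stride's grasps),
#' step width (horizontal distance to the homologue), reach and grasp
#' durations, duty factor (grasp duration over stride duration) and the
#' body speed over the stride window.
#'
#' @name gait
#' @keywords internal
NULL

HOMOLOGUE <- c(rf = "lf", lf = "rf", rh = "lh", lh = "rh")
LIMB_CLASS <- c(rf = "fore", lf = "fore", rh = "hind", lh = "hind")

## path length of a trajectory between two times (inclusive frames)
path_length_between <- function(x, y, time_s, t0, t1) {
  i <- which(time_s >= t0 & time_s <= t1)
  if (length(i) < 2) return(0)
  sum(sqrt(diff(x[i])^2 + diff(y[i])^2))
}

interp_at <- function(time_s, v, t) stats::approx(time_s, v, xout = t, rule = 2)$y

#' Compute stride-level gait metrics for a track
#'
#' @param track a [pose_track()].
#' @param events named list of [limb_events()] per paw (see
#'   [segment_track()]).
#' @param body_speed_window_s unused placeholder kept for configurability;
#'   per-stride body speed uses the stride window itself as the path-length
#'   interval.
#' @return data.frame of stride records with columns `mouse_id`,
#'   `session_id`, `trial_id`, `paw`, `limb_class`, `stride_start_s`,
#'   `stride_end_s`, `reach_length_cm`, `step_length_cm`, `stride_length_cm`,
#'   `step_width_cm`, `reach_duration_s`, `grasp_duration_s`, `duty_factor`,
#'   `body_speed_cm_s`, `location`.
#' @export
compute_stride_metrics <- function(track, events, body_speed_window_s = NULL) {
  t <- track$time_s
  tb <- kp_xy(track, "tail_base")
  step <- sqrt(diff(tb$x)^2 + diff(tb$y)^2)
  cum_path <- c(0, cumsum(step))
  ## paw path length between arbitrary times, via cumulative sums
  rows <- list()
  for (paw in PAWS) {
    ev <- events[[paw]]
    if (is.null(ev)) next
    sw <- stride_windows(ev)
    if (!nrow(sw)) next
    c_ <- kp_xy(track, paw)
    hom <- kp_xy(track, HOMOLOGUE[[paw]])
    paw_cum <- c(0, cumsum(sqrt(diff(c_$x)^2 + diff(c_$y)^2)))
    g0 <- sw$start_s; g1 <- sw$end_s
    ## grasp phase: stride-opening grasp to the next reach initiation;
    ## reach phase: that reach initiation to the stride-closing grasp
    r_all <- ev$reach_onsets_s
    hit <- findInterval(g0, r_all) + 1L  # first reach onset after g0
    r_in <- ifelse(hit <= length(r_all), r_all[hit], NA_real_)
    ok <- !is.na(r_in) & r_in > g0 & r_in < g1
    if (!any(ok)) next
    g0 <- g0[ok]; g1 <- g1[ok]; r_in <- r_in[ok]
    grasp_dur <- r_in - g0
    reach_dur <- g1 - r_in
    y_g0 <- interp_at(t, c_$y, g0); y_g1 <- interp_at(t, c_$y, g1)
    ## homologous-paw comparisons at the stride-opening grasp event
    step_len <- abs(y_g0 - interp_at(t, hom$y, g0))
    step_wid <- abs(interp_at(t, c_$x, g0) - interp_at(t, hom$x, g0))
    reach_len <- interp_at(t, paw_cum, g1) - interp_at(t, paw_cum, r_in)
    ## body speed: tail-base path length over the stride window
    bs <- (interp_at(t, cum_path, g1) - interp_at(t, cum_path, g0)) / (g1 - g0)
    rows[[length(rows) + 1L]] <- data.frame(
      mouse_id = track$meta$mouse_id, session_id = track$meta$session_id,
      trial_id = track$meta$trial_id, paw = paw,
      limb_class = unname(LIMB_CLASS[[paw]]),
      stride_start_s = g0, stride_end_s = g1,
      reach_length_cm = reach_len, step_length_cm = step_len,
      stride_length_cm = abs(y_g1 - y_g0),
      step_width_cm = step_wid,
      reach_duration_s = reach_dur, grasp_duration_s = grasp_dur,
      duty_factor = grasp_dur / (grasp_dur + reach_dur),
      body_speed_cm_s = bs,
      location = "standard", stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(empty_stride_table())
  do.call(rbind, rows)
}

empty_stride_table <- function() {
  data.frame(mouse_id = character(), session_id = character(),
             trial_id = character(), paw = character(),
             limb_class = character(), stride_start_s = numeric(),
             stride_end_s = numeric(), reach_length_cm = numeric(),
             step_length_cm = numeric(), stride_length_cm = numeric(),
             step_width_cm = numeric(), reach_duration_s = numeric(),
             grasp_duration_s = numeric(), duty_factor = numeric(),
             body_speed_cm_s = numeric(), location = character(),
             stringsAsFactors = FALSE)
}

#' Average stride metrics into body-speed bins
#'
#' Strides are assigned to half-open speed bins of width `bin_width`
#' starting at 0, left/right paws pooled within limb class, and each metric
#' averaged per mouse x bin x class (simple unweighted mean over strides).
#' Bins are flagged `inferential` only when at least `min_mice` mice
#' contribute for that limb class; other bins are descriptive.
#'
#' @param records stride table from [compute_stride_metrics()].
#' @param bin_width bin width in cm/s (default 1.6).
#' @param min_mice inclusion threshold for inference (default 8).
#' @return data.frame with one row per mouse x bin x limb class, mean of
#'   each gait metric, `n_strides`, `bin_lo`, `bin_hi`, `inferential`.
#' @export
bin_by_speed <- function(records, bin_width = 1.6, min_mice = 8) {
  records <- records[is.finite(records$body_speed_cm_s), , drop = FALSE]
  if (!nrow(records)) return(records)
  records$speed_bin <- floor(records$body_speed_cm_s / bin_width)
  metrics <- c("reach_length_cm", "step_length_cm", "stride_length_cm",
               "step_width_cm", "reach_duration_s", "grasp_duration_s",
               "duty_factor", "body_speed_cm_s")
  agg <- stats::aggregate(records[metrics],
                          by = list(mouse_id = records$mouse_id,
                                    limb_class = records$limb_class,
                                    speed_bin = records$speed_bin),
                          FUN = mean)
  cnt <- stats::aggregate(list(n_strides = records$duty_factor),
                          by = list(mouse_id = records$mouse_id,
                                    limb_class = records$limb_class,
                                    speed_bin = records$speed_bin),
                          FUN = length)
  agg <- merge(agg, cnt)
  mice_per_bin <- stats::aggregate(
    list(n_mice = agg$mouse_id),
    by = list(limb_class = agg$limb_class, speed_bin = agg$speed_bin),
    FUN = function(x) length(unique(x)))
  agg <- merge(agg, mice_per_bin)
  agg$bin_lo <- agg$speed_bin * bin_width
  agg$bin_hi <- (agg$speed_bin + 1) * bin_width
  agg$inferential <- agg$n_mice >= min_mice
  agg[order(agg$speed_bin, agg$limb_class, agg$mouse_id), ]
}

#' Per-mouse correlation between a gait feature and body speed
#'
#' Pearson (default for roughly linear features: reach length, step length,
#' step width, reach duration, duty factor) or Spearman (grasp duration,
#' whose relation with speed is strongly nonlinear) correlation computed on
#' stride-level data separately for each mouse, summarised as the median and
#' range across mice.
#'
#' @param records stride table.
#' @param feature column name of the feature.
#' @param method `"pearson"` or `"spearman"`.
#' @param limb_class optional `"fore"`/`"hind"` filter.
#' @return list with `per_mouse` (named coefficients), `median`, `range`,
#'   `method`. Mice with fewer than 3 strides are dropped with a warning.
#' @export
feature_speed_correlation <- function(records, feature,
                                      method = c("pearson", "spearman"),
                                      limb_class = NULL) {
  method <- match.arg(method)
  if (!feature %in% names(records))
    stop("feature_speed_correlation(): unknown feature '", feature, "'")
  if (!is.null(limb_class))
    records <- records[records$limb_class == limb_class, , drop = FALSE]
  records <- records[is.finite(records[[feature]]) &
                       is.finite(records$body_speed_cm_s), , drop = FALSE]
  out <- c()
  for (m in unique(records$mouse_id)) {
    sub <- records[records$mouse_id == m, ]
    if (nrow(sub) < 3) {
      warning("feature_speed_correlation(): mouse ", m,
              " has < 3 strides, dropped")
      next
    }
    out[m] <- stats::cor(sub[[feature]], sub$body_speed_cm_s, method = method)
  }
  if (!length(out)) stop("feature_speed_correlation(): no mouse with >= 3 strides")
  list(per_mouse = out, median = stats::median(out), range = range(out),
       method = method)
}
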