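#' Paw event segmentation
#'
#' Reach/grasp segmentation follows the speed-threshold scheme used for
#' climbing gait: smooth each paw's trajectory, take the planar speed
#' magnitude, and use a hysteresis threshold pair to find reach initiations
#' (the last sample before speed rises through the enter threshold) and
#' grasps (the first sample after speed falls through the exit threshold).
#' Slips are maximal runs of strongly negative vertical paw speed.
#'
#' @name events
#' @keywords internal
NULL

#' Moving-average smoothing followed by central-difference differentiation
#'
#' @param positions numeric positions in cm, one per frame.
#' @param frame_rate frames per second.
#' @param window_frames odd smoothing window length (frames).
#' @return speed in cm/s, same length as input (one-sided differences at the
#'   endpoints).
#' @export
smooth_and_differentiate <- function(positions, frame_rate, window_frames = 5) {
  n <- length(positions)
  stopifnot(window_frames >= 1, window_frames %% 2 == 1)
  if (n < max(window_frames, 2))
    stop("smooth_and_differentiate(): sequence shorter than window")
  sm <- moving_average(positions, window_frames)
  dt <- 1 / frame_rate
  v <- numeric(n)
  v[2:(n - 1)] <- (sm[3:n] - sm[1:(n - 2)]) / (2 * dt)
  v[1] <- (sm[2] - sm[1]) / dt
  v[n] <- (sm[n] - sm[n - 1]) / dt
  v
}

## centered moving average with shrinking windows at the edges
moving_average <- function(x, w) {
  if (w == 1) return(x)
  h <- (w - 1) / 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Planar paw speed magnitude
#' @param x,y paw coordinates in cm.
#' @param frame_rate frames per second.
#' @param window_frames smoothing window (odd).
#' @return `sqrt(vx^2 + vy^2)` in cm/s.
#' @export
paw_speed_xy <- function(x, y, frame_rate, window_frames = 5) {
  vx <- smooth_and_differentiate(x, frame_rate, window_frames)
  vy <- smooth_and_differentiate(y, frame_rate, window_frames)
  sqrt(vx^2 + vy^2)
}

#' Limb event series
#'
#' Container for one paw's segmentation: sorted reach-initiation and grasp
#' times that strictly alternate, the derived reach intervals (reach onset to
#' next grasp) and grasp intervals (grasp to next reach onset or trial end),
#' and slip times.
#'
#' @param paw one of `"rf", "lf", "rh", "lh"`.
#' @param reach_onsets_s,grasp_onsets_s sorted event times (s).
#' @param trial_start_s,trial_end_s trial time span, used to close the first
#'   and last grasp intervals.
#' @param slip_times_s sorted slip onset times (s).
#' @return an object of class `limb_events`.
#' @export
limb_events <- function(paw, reach_onsets_s, grasp_onsets_s,
                        trial_start_s, trial_end_s, slip_times_s = numeric()) {
  reach_onsets_s <- sort(reach_onsets_s)
  grasp_onsets_s <- sort(grasp_onsets_s)
  ev <- c(reach_onsets_s, grasp_onsets_s)
  lab <- c(rep("reach", length(reach_onsets_s)),
           rep("grasp", length(grasp_onsets_s)))
  o <- order(ev)
  if (length(ev) > 1 && any(lab[o][-1] == lab[o][-length(ev)]))
    stop("limb_events(): reach and grasp onsets must strictly alternate")
  reach_intervals <- if (length(reach_onsets_s)) {
    nxt <- vapply(reach_onsets_s, function(r) {
      g <- grasp_onsets_s[grasp_onsets_s > r]
      if (length(g)) g[1] else NA_real_
    }, 1.0)
    data.frame(start_s = reach_onsets_s, end_s = nxt)[!is.na(nxt), , drop = FALSE]
  } else data.frame(start_s = numeric(), end_s = numeric())
  g0 <- if (length(grasp_onsets_s) && (!length(reach_onsets_s) ||
        grasp_onsets_s[1] < reach_onsets_s[1])) grasp_onsets_s else
        c(trial_start_s, grasp_onsets_s)
  grasp_intervals <- if (length(g0)) {
    nxt <- vapply(g0, function(g) {
      r <- reach_onsets_s[reach_onsets_s > g]
      if (length(r)) r[1] else trial_end_s
    }, 1.0)
    d <- data.frame(start_s = g0, end_s = nxt)
    d[d$end_s > d$start_s, , drop = FALSE]
  } else data.frame(start_s = numeric(), end_s = numeric())
  structure(list(paw = paw, reach_onsets_s = reach_onsets_s,
                 grasp_onsets_s = grasp_onsets_s,
                 reach_intervals = reach_intervals,
                 grasp_intervals = grasp_intervals,
                 slip_times_s = sort(slip_times_s),
                 trial_start_s = trial_start_s, trial_end_s = trial_end_s),
            class = "limb_events")
}

#' @export
print.limb_events <- function(x, ...) {
  cat(sprintf("limb_events[%s]: %d reaches, %d grasps, %d slips over [%.2f, %.2f] s\n",
              x$paw, length(x$reach_onsets_s), length(x$grasp_onsets_s),
              length(x$slip_times_s), x$trial_start_s, x$trial_end_s))
  invisible(x)
}

#' Detect reach and grasp events from a paw speed trace
#'
#' Hysteresis thresholding: the paw enters the reach (moving) state when
#' speed rises through `enter_thresh` and returns to the grasp (stationary)
#' state when speed falls through `exit_thresh` (`enter_thresh >=
#' exit_thresh` suppresses chatter). The reach onset is the last sample
#' before the rise; the grasp onset the first sample after the fall. Moving
#' or stationary episodes shorter than `min_event_s` are merged into their
#' neighbours before timestamps are extracted. An all-stationary trace is
#' valid: zero reaches, one grasp interval spanning the trial.
#'
#' @param paw_speed speed magnitude in cm/s, one per frame.
#' @param time_s frame times (s).
#' @param enter_thresh,exit_thresh hysteresis pair in cm/s.
#' @param min_event_s minimum episode duration in seconds.
#' @param paw paw label carried into the result.
#' @return a [limb_events()] (without slips; see [detect_slips()]).
#' @export
detect_events <- function(paw_speed, time_s, enter_thresh = 2,
                          exit_thresh = 1, min_event_s = 0.025, paw = "rf") {
  stopifnot(length(paw_speed) == length(time_s),
            enter_thresh >= exit_thresh, exit_thresh > 0)
  n <- length(paw_speed)
  ## hysteresis state per sample: TRUE = moving (reach phase)
  state <- logical(n)
  cur <- paw_speed[1] > enter_thresh
  for (i in seq_len(n)) {
    if (cur) {
      if (paw_speed[i] < exit_thresh) cur <- FALSE
    } else {
      if (paw_speed[i] > enter_thresh) cur <- TRUE
    }
    state[i] <- cur
  }
  dt <- if (n > 1) stats::median(diff(time_s)) else 0
  min_frames <- max(1, round(min_event_s / dt))
  ## merge short episodes into neighbours (moving blips first, then pauses)
  state <- drop_short_runs(state, TRUE, min_frames)
  state <- drop_short_runs(state, FALSE, min_frames)
  trans <- diff(state)
  rise <- which(trans == 1)        # last stationary sample before moving
  fall <- which(trans == -1) + 1L  # first stationary sample after moving
  reach <- time_s[rise]
  grasp <- time_s[fall]
  ## enforce alternation: a leading moving state has no reach onset, a
  ## trailing moving state has no grasp; trim unmatched edge events
  if (length(grasp) && (!length(reach) || grasp[1] < reach[1]))
    grasp <- grasp  # leading grasp is fine (trial starts mid-reach)
  limb_events(paw, reach, grasp, time_s[1], time_s[n])
}

## flip runs of `value` shorter than min_len (interior runs only for edges
## we keep the observed state: a short leading pause is real trial context)
drop_short_runs <- function(state, value, min_len) {
  runs <- rle(state)
  k <- length(runs$lengths)
  if (k < 2) return(state)
  for (j in seq_len(k)) {
    if (runs$values[j] == value && runs$lengths[j] < min_len && j > 1 && j < k)
      runs$values[j] <- !value
  }
  inverse.rle(within.rle_merge(runs))
}

## re-merge adjacent equal-valued runs after flipping
within.rle_merge <- function(runs) {
  v <- runs$values; l <- runs$lengths
  keep_v <- v[1]; keep_l <- l[1]
  out_v <- c(); out_l <- c()
  for (j in seq_along(v)[-1]) {
    if (v[j] == keep_v) keep_l <- keep_l + l[j]
    else { out_v <- c(out_v, keep_v); out_l <- c(out_l, keep_l)
           keep_v <- v[j]; keep_l <- l[j] }
  }
  structure(list(lengths = c(out_l, keep_l), values = c(out_v, keep_v)),
            class = "rle")
}

#' Detect paw slips from signed vertical speed
#'
#' A slip is a maximal contiguous run of frames where the signed vertical
#' paw speed (positive = upward) lies strictly below `slip_thresh`
#' (default -10 cm/s, i.e. rapid downward motion).
#'
#' @param paw_vertical_speed signed vertical speed in cm/s.
#' @param time_s frame times (s).
#' @param slip_thresh threshold in cm/s (negative).
#' @return list with `count` and `times_s` (run onsets).
#' @export
detect_slips <- function(paw_vertical_speed, time_s, slip_thresh = -10) {
  if (!length(paw_vertical_speed)) return(list(count = 0L, times_s = numeric()))
  below <- paw_vertical_speed < slip_thresh
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  onset <- starts[runs$values]
  list(count = length(onset), times_s = time_s[onset])
}

#' Instantaneous body speed from the tail-base path length
#'
#' Speed at each frame is the tail-base path length accumulated over a
#' centred window of width `window_s`, divided by the window duration
#' (windows shrink one-sidedly at trial edges). The tail base tracks the
#' torso and is insensitive to individual limb movements.
#'
#' @param track a [pose_track()].
#' @param window_s window width in seconds.
#' @return cm/s per frame.
#' @export
body_speed <- function(track, window_s = 0.5) {
  tb <- kp_xy(track, "tail_base")
  t <- track$time_s
  if (window_s >= t[length(t)] - t[1])
    stop("body_speed(): window longer than trial")
  step <- sqrt(diff(tb$x)^2 + diff(tb$y)^2)
  cum <- c(0, cumsum(step))
  h <- window_s / 2
  lo <- findInterval(t - h, t)
  hi <- findInterval(t + h, t)
  lo <- pmax(lo, 1L); hi <- pmin(hi, length(t))
  span <- t[hi] - t[lo]
  span[span <= 0] <- NA_real_
  (cum[hi] - cum[lo]) / span
}

#' Trial climbing speed over a fixed 20-cm band
#'
#' Overall climb speed is measured over a fixed vertical band to absorb
#' differences in starting position: `20 / (t_exit - t_enter)` where the
#' times are the first upward crossings of the band bottom and top by the
#' tail base. A trial that never traverses the whole band is flagged as
#' excluded rather than erroring.
#'
#' @param track a [pose_track()].
#' @param band_bottom_cm y of the band bottom.
#' @param band_height_cm band height (default 20).
#' @return list with `speed_cm_s` (NA when excluded), `excluded`,
#'   `t_enter_s`, `t_exit_s`.
#' @export
trial_speed_20cm <- function(track, band_bottom_cm = 10, band_height_cm = 20) {
  y <- kp_xy(track, "tail_base")$y
  t <- track$time_s
  top <- band_bottom_cm + band_height_cm
  enter <- which(y[-1] >= band_bottom_cm & y[-length(y)] < band_bottom_cm)
  out <- list(speed_cm_s = NA_real_, excluded = TRUE,
              t_enter_s = NA_real_, t_exit_s = NA_real_)
  if (y[1] >= band_bottom_cm) enter <- c(0L, enter)  # starts inside band
  if (!length(enter)) return(out)
  i0 <- enter[1] + 1L
  exit <- which(y[-1] >= top & y[-length(y)] < top)
  exit <- exit[exit >= i0]
  if (!length(exit)) return(out)
  t0 <- t[i0]; t1 <- t[exit[1] + 1L]
  list(speed_cm_s = band_height_cm / (t1 - t0), excluded = FALSE,
       t_enter_s = t0, t_exit_s = t1)
}

#' Stride windows for one paw
#'
#' A stride spans the time between consecutive grasp events of the same paw.
#'
#' @param events a [limb_events()].
#' @return data.frame with `start_s`, `end_s`, one row per stride (empty when
#'   fewer than two grasps).
#' @export
stride_windows <- function(events) {
  g <- events$grasp_onsets_s
  if (length(g) < 2)
    return(data.frame(start_s = numeric(), end_s = numeric()))
  data.frame(start_s = g[-length(g)], end_s = g[-1])
}

#' Sub-frame refinement of reach and grasp onsets
#'
#' Threshold crossings on a smoothed speed trace are systematically early
#' (rise) or late (fall) by up to the smoothing half-width, which inflates
#' reach durations and biases the duty factor. Because the paw's speed
#' rises and falls approximately linearly near an event, extrapolating the
#' tangent of the speed edge (taken at a high fraction of the movement's
#' peak speed, outside the kernel-smeared zone) down to zero speed recovers
#' the true transition time, and a centred moving average preserves linear
#' segments exactly. Each coarse onset is replaced by this extrapolated
#' time, clamped to a window around the coarse estimate.
#'
#' @param events a [limb_events()] from [detect_events()].
#' @param speed smoothed speed magnitude, or a list of such traces (named
#'   by their window length in frames) from which the refinement picks the
#'   widest window whose half-width still fits inside each movement: short,
#'   fast reaches get a short window (their high peak speed swamps the
#'   noise), long slow reaches a wider one.
#' @param time_s frame times.
#' @param enter_thresh floor for the refinement threshold.
#' @param frac fractions of the movement's peak speed at which the two
#'   chord crossings are taken.
#' @param clamp_frames maximum correction in frames.
#' @return the refined [limb_events()].
#' @export
refine_events <- function(events, speed, time_s, enter_thresh = 2,
                          frac = c(0.30, 0.55), clamp_frames = 8) {
  dt <- stats::median(diff(time_s))
  traces <- if (is.list(speed)) speed else list(speed)
  if (is.null(names(traces)) || any(!nzchar(names(traces))))
    names(traces) <- as.character(seq(3, by = 2, length.out = length(traces)))
  widths <- as.numeric(names(traces))
  n <- length(traces[[1]])
  idx_of <- function(tt) max(1L, min(n, which.min(abs(time_s - tt))))
  ## first upward crossing of th in [i0, i1], sub-frame by interpolation
  rise_cross <- function(speed, i0, i1, th) {
    up <- which(speed[i0:i1] >= th)
    if (!length(up)) return(NA_real_)
    ic <- i0 + up[1] - 1L
    if (ic == 1L || speed[ic] == speed[ic - 1L]) return(time_s[ic])
    time_s[ic - 1L] + (th - speed[ic - 1L]) / (speed[ic] - speed[ic - 1L]) * dt
  }
  ## last downward crossing of th in [i0, i1]
  fall_cross <- function(speed, i0, i1, th) {
    up <- which(speed[i0:i1] >= th)
    if (!length(up)) return(NA_real_)
    ic <- i0 + up[length(up)] - 1L
    if (ic >= n || speed[ic] == speed[ic + 1L]) return(time_s[ic])
    time_s[ic] + (th - speed[ic]) / (speed[ic + 1L] - speed[ic]) * dt
  }
  ## Onset from two points on the rising edge of a boxcar-smoothed linear
  ## speed ramp. A width-2H boxcar turns v = a*(t - t0) (0 before t0) into
  ## a quadratic a*(t - t0 + H)^2 / 4H on [t0 - H, t0 + H] and back into
  ## the exact line beyond t0 + H, so the model is invertible: first try
  ## the straight chord; if it places the lower crossing inside the smear
  ## zone, re-solve with the lower point on the quadratic branch.
  edge_onset <- function(t1, v1, t2, v2, H) {
    if (v2 <= v1 || t2 <= t1) return(NA_real_)
    t0 <- t1 - v1 * (t2 - t1) / (v2 - v1)
    if (H <= 0 || t1 - t0 >= H) return(t0)
    cc <- t1 + H
    A <- v2; B <- -2 * v2 * cc + 4 * H * v1
    C <- v2 * cc^2 - 4 * H * v1 * t2
    disc <- B^2 - 4 * A * C
    if (disc < 0) return(t0)
    roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
    roots <- roots[roots < t1 + 1e-12]
    if (!length(roots)) t0 else max(roots)
  }
  riv <- events$reach_intervals
  if (!nrow(riv)) return(events)
  new_r <- events$reach_onsets_s
  new_g <- events$grasp_onsets_s
  for (k in seq_len(nrow(riv))) {
    i0 <- max(1L, idx_of(riv$start_s[k]) - 4L)
    i1 <- min(n, idx_of(riv$end_s[k]) + 4L)
    if (i1 - i0 < 4) next
    ## choose the widest trace whose smear zone (~half window) stays inside
    ## the first ~15% of the movement, where the chord crossings live
    dur <- i1 - i0 - 8
    fit <- widths[widths <= max(3, dur / 4)]
    w_use <- if (length(fit)) as.character(max(fit)) else names(traces)[1]
    speed <- traces[[w_use]]
    vp <- max(speed[i0:i1])
    th1 <- max(enter_thresh, frac[1] * vp)
    th2 <- max(enter_thresh * 1.5, frac[2] * vp)
    if (th2 <= th1) next
    ## effective kernel half-width: boxcar (w-1)/2 plus one frame from the
    ## central difference
    H <- (as.numeric(w_use) + 1) / 2 * dt
    ## rising edge: chord through the two threshold crossings extrapolated
    ## to zero speed, inverting the kernel smear when the lower crossing
    ## falls inside the smeared zone
    t1 <- rise_cross(speed, i0, i1, th1); t2 <- rise_cross(speed, i0, i1, th2)
    if (is.finite(t1) && is.finite(t2) && t2 > t1) {
      t_new <- edge_onset(t1, th1, t2, th2, H)
      j <- which(new_r == riv$start_s[k])[1]
      if (!is.na(j) && is.finite(t_new) &&
          abs(t_new - new_r[j]) <= clamp_frames * dt)
        new_r[j] <- t_new
    }
    ## falling edge: mirror image (time reversed)
    t1 <- fall_cross(speed, i0, i1, th1); t2 <- fall_cross(speed, i0, i1, th2)
    if (is.finite(t1) && is.finite(t2) && t1 > t2) {
      t_new <- -edge_onset(-t1, th1, -t2, th2, H)
      j <- which(new_g == riv$end_s[k])[1]
      if (!is.na(j) && is.finite(t_new) &&
          abs(t_new - new_g[j]) <= clamp_frames * dt)
        new_g[j] <- t_new
    }
  }
  ## rebuild, dropping any pair whose refined order collapsed
  o <- order(c(new_r, new_g))
  lab <- c(rep("r", length(new_r)), rep("g", length(new_g)))[o]
  tt <- c(new_r, new_g)[o]
  keep <- rep(TRUE, length(tt))
  for (j in seq_along(tt)[-1]) if (lab[j] == lab[j - 1]) keep[j] <- FALSE
  limb_events(events$paw, tt[keep & lab == "r"], tt[keep & lab == "g"],
              events$trial_start_s, events$trial_end_s, events$slip_times_s)
}

#' Segment all four paws of a track
#'
#' Convenience wrapper: smooths each paw, runs [detect_events()] on the
#' planar speed magnitude (a wider detection window keeps tracking noise
#' below the hysteresis thresholds), refines onsets to sub-frame precision
#' with [refine_events()] on a short-window speed trace, and runs
#' [detect_slips()] on the signed vertical speed.
#'
#' @param track a [pose_track()].
#' @param enter_thresh,exit_thresh,min_event_s see [detect_events()].
#' @param window_frames detection smoothing window.
#' @param slip_thresh see [detect_slips()].
#' @param refine apply sub-frame onset refinement.
#' @param refine_window candidate smoothing windows for the refinement
#'   speed traces; [refine_events()] picks per movement.
#' @return named list of [limb_events()], one per paw.
#' @export
segment_track <- function(track, enter_thresh = 2, exit_thresh = 1,
                          min_event_s = 0.025, window_frames = 13,
                          slip_thresh = -10, refine = TRUE,
                          refine_window = c(3, 5, 7)) {
  fr <- track$cal$frame_rate_hz
  out <- list()
  for (paw in PAWS) {
    c_ <- kp_xy(track, paw)
    sp <- paw_speed_xy(c_$x, c_$y, fr, window_frames)
    ev <- detect_events(sp, track$time_s, enter_thresh, exit_thresh,
                        min_event_s, paw = paw)
    if (refine && length(ev$reach_onsets_s)) {
      sp_fine <- lapply(refine_window, function(w)
        paw_speed_xy(c_$x, c_$y, fr, w))
      names(sp_fine) <- as.character(refine_window)
      ev <- refine_events(ev, sp_fine, track$time_s, enter_thresh)
    }
    ## slips are brief (a few frames); a short window preserves their
    ## vertical-speed excursion while staying above the noise floor
    vy <- smooth_and_differentiate(c_$y, fr, 5)
    sl <- detect_slips(vy, track$time_s, slip_thresh)
    ev$slip_times_s <- sl$times_s
    out[[paw]] <- ev
  }
  out
}
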