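#' Synthetic climbing cohorts with known ground truth
#'
#' The simulator inverts the measurement model of the analysis pipeline: a
#' virtual mouse ascends a 22.5 x 40 cm wall at 200 fps, its body (tail
#' base) integrating a piecewise speed profile with optional idle pauses,
#' while each limb cycles through a reach (smooth vertical advance) and a
#' grasp (stationary hold) phase. Limb cycles are tied to body progress so
#' that one cycle corresponds to one stride length; each limb's cycle is
#' offset by a configurable phase lag (forelimbs anti-phase, hindlimbs
#' in-phase by default), with per-mouse heterogeneity and per-cycle jitter.
#' Tracking noise, confidence dropouts and occasional slips are layered on
#' top, and a gap-wall variant switches coordination parameters inside a
#' horizontal band the paws cannot grip. Every true event time, lag, duty
#' factor and slip is recorded as ground truth.
#'
#' @name synthetic_data
#' @keywords internal
NULL

#' Simulation configuration
#'
#' Defaults describe the cohort scale and kinematics the analysis targets:
#' 10 mice, 8 sessions of 10 climbs, body speeds drawn around 7.7 +/- 2.4
#' cm/s truncated to 0.7-13 cm/s, duty factor d(v) = d0 - c v in the
#' 0.4-0.8 range, forelimb phase lag 0.5 (anti-phase), hindlimb lag 0
#' (in-phase), diagonal lag 0.05, hindpaw stance wider than forepaw.
#'
#' @param n_mice,sessions_per_mouse,climbs_per_session cohort size.
#' @param frame_rate_hz acquisition rate (200).
#' @param wall_width_cm,wall_height_cm wall dimensions (22.5 x 40).
#' @param stride_length_cm body advance per limb cycle.
#' @param duty_d0 duty factor at zero speed.
#' @param duty_speed_coupling linear decrease of duty factor per cm/s.
#' @param phase_lags list with `FF`, `HH`, `diag` lags in cycles `[0, 1)`:
#'   `lf = rf + FF`, `lh = rf + diag`, `rh = lh + HH`.
#' @param phase_lag_sd_mouse between-mouse SD of each lag (cycles).
#' @param cycle_skip_prob per limb-cycle probability that the paw holds
#'   through the cycle and reaches two rungs on the next one. Skips break
#'   the perfect limb-cycle symmetry, giving mouse-level phase means the
#'   between-mouse spread that the group-level circular tests assume.
#' @param phase_jitter_sd per-cycle timing jitter as a fraction of the
#'   cycle period (truncated at 2 sd). The default 0.15 reproduces the
#'   broad sample-level phase dispersion of real climbing (pairwise
#'   resultant lengths around 0.2-0.4) rather than clockwork cycles.
#' @param speed_mean_cm_s,speed_sd_cm_s,speed_range_cm_s climb-speed draw
#'   (truncated normal).
#' @param idle_prob probability a climb contains an idle pause.
#' @param idle_duration_s range of idle durations.
#' @param fore_step_width_cm,hind_step_width_cm lane separations.
#' @param noise_sd_cm isotropic tracking noise SD.
#' @param dropout_prob per frame-keypoint probability of a low-confidence
#'   dropout.
#' @param slip_rate mean slips per climb (Poisson).
#' @param gap `NULL`, or a list with `gap_bottom_cm`, `gap_height_cm`
#'   (3.4), `success_prob`, and `at_gap_phase_lags` (lag overrides applied
#'   to cycles near/within the band).
#' @param seed RNG seed for [simulate_cohort()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_mice = 10, sessions_per_mouse = 8,
                       climbs_per_session = 10, frame_rate_hz = 200,
                       wall_width_cm = 22.5, wall_height_cm = 40,
                       stride_length_cm = 2.5,
                       duty_d0 = 0.75, duty_speed_coupling = 0.02,
                       phase_lags = list(FF = 0.5, HH = 0.0, diag = 0.05),
                       phase_lag_sd_mouse = 0.02, phase_jitter_sd = 0.05,
                       cycle_skip_prob = 0.05,
                       speed_mean_cm_s = 7.7, speed_sd_cm_s = 2.4,
                       speed_range_cm_s = c(0.7, 13),
                       idle_prob = 0.25, idle_duration_s = c(0.5, 2),
                       fore_step_width_cm = 1.8, hind_step_width_cm = 3.0,
                       noise_sd_cm = 0.03, dropout_prob = 0.002,
                       slip_rate = 0.2, gap = NULL, seed = 1L) {
  d_lo <- duty_d0 - duty_speed_coupling * speed_range_cm_s[2]
  if (duty_d0 >= 1 || duty_d0 <= 0 || d_lo <= 0)
    stop("sim_config(): infeasible duty factor parameters")
  if (any(unlist(phase_lags) < 0) || any(unlist(phase_lags) >= 1))
    stop("sim_config(): phase lags must lie in [0, 1)")
  if (speed_range_cm_s[1] <= 0 && idle_prob <= 0)
    stop("sim_config(): zero speed with no idle periods is infeasible")
  if (!is.null(gap)) {
    gap <- utils::modifyList(
      list(gap_bottom_cm = 18, gap_height_cm = 3.4, success_prob = 0.8,
           at_gap_phase_lags = list(FF = 0.5, HH = 0.5, diag = 0.05),
           approach_cm = 4), gap)
    if (gap$gap_bottom_cm <= 0 ||
        gap$gap_bottom_cm + gap$gap_height_cm >= wall_height_cm)
      stop("sim_config(): gap band outside the wall")
  }
  structure(as.list(environment()), class = "sim_config")
}

## effective per-limb cycle lags for a mouse (cycles in [0, 1)). The
## per-mouse deviations are drawn once and attached, so that alternative
## lag sets (the at-gap overrides) can be realized for the same mouse
## consistently.
limb_lags <- function(lags, sd_mouse = 0) {
  deltas <- stats::rnorm(3, 0, sd_mouse)
  names(deltas) <- c("FF", "HH", "diag")
  out <- lags_with_deltas(lags, deltas)
  attr(out, "deltas") <- deltas
  out
}

lags_with_deltas <- function(lags, deltas) {
  rf <- 0
  lf <- (lags$FF + deltas[["FF"]]) %% 1
  lh <- (lags$diag + deltas[["diag"]]) %% 1
  rh <- (lh + lags$HH + deltas[["HH"]]) %% 1
  c(rf = rf, lf = lf, rh = rh, lh = lh)
}

## first frame index at which nondecreasing x reaches each target
invert_monotone <- function(x, targets) {
  idx <- findInterval(targets, x, left.open = TRUE) + 1L
  idx[idx > length(x)] <- NA_integer_
  idx
}

## cosine-eased interpolation of a paw between hold positions
ease <- function(s) (1 - cos(pi * pmin(pmax(s, 0), 1))) / 2

#' Simulate one climb
#'
#' @param cfg a [sim_config()].
#' @param mouse_lags named per-limb lags for this mouse (from the cohort
#'   level); defaults to the configured lags without heterogeneity.
#' @param meta metadata list (mouse/session/trial ids, wall type).
#' @param attempt for gap walls: force an attempted (failed) cross.
#' @return list with `track` (a [pose_track()]) and `truth` (per-paw true
#'   reach/grasp onsets, per-cycle duty factors and at-gap flags, slip
#'   table, climb speed, outcome).
#' @export
simulate_trial <- function(cfg, mouse_lags = NULL, meta = list(),
                           attempt = FALSE) {
  fr <- cfg$frame_rate_hz; dt <- 1 / fr
  if (is.null(mouse_lags)) mouse_lags <- limb_lags(cfg$phase_lags, 0)
  deltas <- attr(mouse_lags, "deltas")
  if (is.null(deltas)) deltas <- c(FF = 0, HH = 0, diag = 0)
  gap <- cfg$gap
  gap_lags <- if (!is.null(gap))
    lags_with_deltas(gap$at_gap_phase_lags, deltas)
  ## climb speed and frame-wise body speed profile
  v_climb <- 0
  while (v_climb < cfg$speed_range_cm_s[1] || v_climb > cfg$speed_range_cm_s[2])
    v_climb <- stats::rnorm(1, cfg$speed_mean_cm_s, cfg$speed_sd_cm_s)
  y0 <- 2
  y_top <- if (!is.null(gap) && attempt) gap$gap_bottom_cm - 2.5
           else cfg$wall_height_cm - 2
  move_t <- (y_top - y0) / v_climb
  n_move <- ceiling(move_t * fr)
  v <- rep(v_climb, n_move)
  if (stats::runif(1) < cfg$idle_prob) {
    d_idle <- stats::runif(1, cfg$idle_duration_s[1], cfg$idle_duration_s[2])
    at <- sample.int(n_move - 1, 1)
    v <- append(v, rep(0, round(d_idle * fr)), after = at)
  }
  ## tail-up pause at the end (and a probe for attempts)
  v <- c(v, rep(0, round(0.5 * fr)))
  n <- length(v)
  t <- (seq_len(n) - 1) * dt
  y_body <- y0 + cumsum(v) * dt
  phase <- (y_body - y0) / cfg$stride_length_cm  # global cycle phase

  lanes <- c(rf = +cfg$fore_step_width_cm / 2, lf = -cfg$fore_step_width_cm / 2,
             rh = +cfg$hind_step_width_cm / 2, lh = -cfg$hind_step_width_cm / 2)
  y_off <- c(rf = 3, lf = 3, rh = -2, lh = -2)
  xc <- cfg$wall_width_cm / 2
  coords <- list()
  truth_events <- list()
  n_cycles_max <- floor(max(phase))
  for (paw in PAWS) {
    lag <- mouse_lags[[paw]]
    ## cycle boundary targets; near the gap band, lag overrides apply
    targets <- numeric(); at_gap_cyc <- logical()
    k <- 0
    while (TRUE) {
      lag_k <- lag
      is_gap <- FALSE
      if (!is.null(gap) && !attempt) {
        y_k <- y0 + (k + lag) * cfg$stride_length_cm + y_off[[paw]]
        if (y_k > gap$gap_bottom_cm - gap$approach_cm &&
            y_k < gap$gap_bottom_cm + gap$gap_height_cm + 1) {
          lag_k <- gap_lags[[paw]]
          is_gap <- TRUE
        }
      }
      tg <- k + lag_k
      if (tg > max(phase)) break
      targets <- c(targets, tg); at_gap_cyc <- c(at_gap_cyc, is_gap)
      k <- k + 1
      if (k > n_cycles_max + 2) break
    }
    ## occasional cycle skips: the paw holds through a cycle and covers
    ## two rungs with the next reach
    if (cfg$cycle_skip_prob > 0 && length(targets) > 3) {
      interior <- seq(2, length(targets) - 1)
      drop <- interior[stats::runif(length(interior)) < cfg$cycle_skip_prob]
      if (length(drop)) {
        targets <- targets[-drop]; at_gap_cyc <- at_gap_cyc[-drop]
      }
    }
    idx <- invert_monotone(phase, targets)
    ok <- !is.na(idx)
    idx <- idx[ok]; at_gap_cyc <- at_gap_cyc[ok]
    ## per-cycle timing jitter (truncated at 2 sd so cycles stay ordered);
    ## the default magnitude reproduces the broad phase dispersion seen in
    ## real climbing rather than clockwork limb cycles
    T_nom <- cfg$stride_length_cm / v_climb
    jit <- stats::rnorm(length(idx), 0, cfg$phase_jitter_sd * T_nom)
    lim <- 2 * cfg$phase_jitter_sd * T_nom
    t_bound <- t[idx] + pmin(pmax(jit, -lim), lim)
    t_bound <- pmin(pmax(sort(t_bound), t[1]), t[n])
    if (length(t_bound) < 3) {
      ## degenerate climb: paw just rides the body
      coords[[paw]] <- list(x = rep(xc + lanes[[paw]], n),
                            y = y_body + y_off[[paw]], conf = rep(1, n))
      truth_events[[paw]] <- list(reach_onsets_s = numeric(),
                                  grasp_onsets_s = numeric(),
                                  duty = numeric(), at_gap = logical())
      next
    }
    n_cyc <- length(t_bound) - 1
    T_k <- diff(t_bound)
    d_k <- pmin(pmax(cfg$duty_d0 - cfg$duty_speed_coupling * v_climb, 0.05), 0.95)
    d_k <- rep(d_k, n_cyc)
    reach_on <- t_bound[-length(t_bound)]
    grasp_on <- reach_on + (1 - d_k) * T_k
    ## grasp target positions: body position at grasp + offset; pushed out
    ## of an ungrippable gap band
    y_hold <- y0 + (targets[ok][-1]) * cfg$stride_length_cm + y_off[[paw]] +
      stats::rnorm(n_cyc, 0, 0.05)
    y_first <- y0 + targets[ok][1] * cfg$stride_length_cm + y_off[[paw]] -
      cfg$stride_length_cm
    if (!is.null(gap)) {
      ## holds cannot land on the ungrippable band: reach across to just
      ## above it; later holds keep a minimum spacing so every cycle still
      ## produces a real (detectable) paw movement
      gb <- gap$gap_bottom_cm; gt <- gb + gap$gap_height_cm
      inside <- y_hold > gb & y_hold < gt
      y_hold[inside] <- gt + 0.3 + stats::runif(sum(inside), 0, 0.3)
      if (n_cyc > 1) for (c_ in 2:n_cyc)
        y_hold[c_] <- max(y_hold[c_], y_hold[c_ - 1] + 0.5)
    }
    x_hold <- xc + lanes[[paw]] + stats::rnorm(n_cyc, 0, 0.1)
    ## assemble paw trajectory: hold during grasp, eased advance in reach
    y_paw <- numeric(n); x_paw <- numeric(n)
    i_pre <- t < reach_on[1]
    y_paw[i_pre] <- y_first; x_paw[i_pre] <- xc + lanes[[paw]]
    prev_y <- y_first; prev_x <- xc + lanes[[paw]]
    for (c_ in seq_len(n_cyc)) {
      ir <- t >= reach_on[c_] & t < grasp_on[c_]
      s <- (t[ir] - reach_on[c_]) / (grasp_on[c_] - reach_on[c_])
      y_paw[ir] <- prev_y + (y_hold[c_] - prev_y) * ease(s)
      x_paw[ir] <- prev_x + (x_hold[c_] - prev_x) * ease(s)
      end_t <- if (c_ < n_cyc) reach_on[c_ + 1] else t[n] + dt
      ig <- t >= grasp_on[c_] & t < end_t
      y_paw[ig] <- y_hold[c_]; x_paw[ig] <- x_hold[c_]
      prev_y <- y_hold[c_]; prev_x <- x_hold[c_]
    }
    coords[[paw]] <- list(x = x_paw, y = y_paw, conf = rep(1, n))
    truth_events[[paw]] <- list(reach_onsets_s = reach_on,
                                grasp_onsets_s = grasp_on,
                                duty = d_k, at_gap = at_gap_cyc[-1][seq_len(n_cyc)])
  }
  ## slips: a brief rapid drop and slower recovery inside a grasp hold
  slips <- data.frame(paw = character(), time_s = numeric(),
                      stringsAsFactors = FALSE)
  n_slips <- stats::rpois(1, cfg$slip_rate)
  for (s_ in seq_len(n_slips)) {
    paw <- sample(PAWS, 1)
    ev <- truth_events[[paw]]
    if (length(ev$grasp_onsets_s) < 2) next
    c_ <- sample(seq_len(length(ev$grasp_onsets_s) - 1), 1)
    g <- ev$grasp_onsets_s[c_]
    nxt <- ev$reach_onsets_s[ev$reach_onsets_s > g]
    if (!length(nxt) || nxt[1] - g < 0.2) next
    t_slip <- g + 0.05
    i0 <- which.min(abs(t - t_slip))
    drop_frames <- 4; rec_frames <- 12
    if (i0 + drop_frames + rec_frames >= n) next
    prof <- c(seq(0, -0.5, length.out = drop_frames + 1)[-1],
              seq(-0.5, 0, length.out = rec_frames + 1)[-1])
    j <- i0 + seq_along(prof)
    coords[[paw]]$y[j] <- coords[[paw]]$y[j] + prof
    slips <- rbind(slips, data.frame(paw = paw, time_s = t[i0],
                                     stringsAsFactors = FALSE))
  }
  ## nose and tail base; for attempts the nose probes above the gap bottom
  nose_y <- y_body + 5 + 0.1 * sin(2 * pi * t)
  if (!is.null(gap) && attempt) {
    probe <- t > t[n] - 0.5
    nose_y[probe] <- gap$gap_bottom_cm + 1 +
      0.5 * sin(2 * pi * (t[probe] - t[n] + 0.5))
  }
  coords$nose <- list(x = rep(xc, n) + stats::rnorm(n, 0, 0.05),
                      y = nose_y, conf = rep(1, n))
  coords$tail_base <- list(x = rep(xc, n) + stats::rnorm(n, 0, 0.05),
                           y = y_body, conf = rep(1, n))
  ## tracking noise and dropouts
  for (kp in KEYPOINTS) {
    m <- length(coords[[kp]]$x)
    coords[[kp]]$x <- coords[[kp]]$x + stats::rnorm(m, 0, cfg$noise_sd_cm)
    coords[[kp]]$y <- coords[[kp]]$y + stats::rnorm(m, 0, cfg$noise_sd_cm)
    if (cfg$dropout_prob > 0) {
      drop <- stats::runif(m) < cfg$dropout_prob
      drop[1] <- drop[m] <- FALSE
      coords[[kp]]$x[drop] <- NA_real_
      coords[[kp]]$y[drop] <- NA_real_
      coords[[kp]]$conf[drop] <- stats::runif(sum(drop), 0, 0.4)
    }
  }
  meta <- utils::modifyList(
    list(mouse_id = "mouse01", session_id = "s01", trial_id = "t01",
         wall_type = if (is.null(gap)) "standard" else "gap"), meta)
  cal <- calibration(frame_rate_hz = fr, wall_width_cm = cfg$wall_width_cm,
                     wall_height_cm = cfg$wall_height_cm)
  track <- pose_track(t, coords, meta = meta, cal = cal)
  truth <- list(events = truth_events, slips = slips, v_climb = v_climb,
                lags = mouse_lags,
                outcome = if (is.null(gap)) NA_character_
                          else if (attempt) "attempt" else "success")
  list(track = track, truth = truth)
}

#' Simulate a full cohort
#'
#' Draws per-mouse limb lags once, then generates every
#' mouse x session x climb trial. With a gap configuration, each climb is a
#' successful cross with probability `gap$success_prob` and an attempted
#' cross otherwise. Identical config and seed give identical output.
#'
#' @param cfg a [sim_config()].
#' @param dir optional directory; when given, per-trial keypoint CSVs and a
#'   `manifest.csv` are written there.
#' @return list with `trials` (list of `simulate_trial()` results),
#'   `manifest` (data.frame: mouse_id, session_id, trial_id, wall_type,
#'   outcome, file), `mouse_lags`, and `cfg`.
#' @export
simulate_cohort <- function(cfg, dir = NULL) {
  set.seed(cfg$seed)
  lag_tab <- lapply(seq_len(cfg$n_mice), function(i)
    limb_lags(cfg$phase_lags, cfg$phase_lag_sd_mouse))
  names(lag_tab) <- sprintf("mouse%02d", seq_len(cfg$n_mice))
  trials <- list(); rows <- list()
  for (i in seq_len(cfg$n_mice)) {
    mid <- sprintf("mouse%02d", i)
    for (s_ in seq_len(cfg$sessions_per_mouse)) {
      for (k in seq_len(cfg$climbs_per_session)) {
        meta <- list(mouse_id = mid, session_id = sprintf("s%02d", s_),
                     trial_id = sprintf("t%02d", k))
        attempt <- !is.null(cfg$gap) && stats::runif(1) > cfg$gap$success_prob
        tr <- simulate_trial(cfg, mouse_lags = lag_tab[[mid]], meta = meta,
                             attempt = attempt)
        file <- sprintf("%s_%s_%s_%s.csv", mid, meta$session_id,
                        meta$trial_id, tr$track$meta$wall_type)
        if (!is.null(dir)) {
          if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
          write_trial(tr$track, file.path(dir, file))
        }
        trials[[length(trials) + 1L]] <- tr
        rows[[length(rows) + 1L]] <- data.frame(
          mouse_id = mid, session_id = meta$session_id,
          trial_id = meta$trial_id, wall_type = tr$track$meta$wall_type,
          outcome = tr$truth$outcome, file = file, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir))
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  list(trials = trials, manifest = manifest, mouse_lags = lag_tab, cfg = cfg)
}
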