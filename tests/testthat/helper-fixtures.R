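# Shared fixtures: tiny deterministic tracks and small simulated cohorts.

# A hand-built track where every keypoint follows a simple analytic path.
make_linear_track <- function(n = 400, fr = 200, v = 5, y0 = 2) {
  t <- (seq_len(n) - 1) / fr
  mk <- function(x0, dy) list(x = rep(x0, n), y = y0 + dy + v * t,
                              conf = rep(1, n))
  pose_track(
    t,
    list(nose = mk(11, 5), tail_base = mk(11, 0),
         rf = mk(12, 3), lf = mk(10, 3), rh = mk(13, -2), lh = mk(9, -2)),
    meta = list(mouse_id = "m1", session_id = "s1", trial_id = "t1"),
    cal = calibration(frame_rate_hz = fr))
}

# Periodic reach onset trains with a fixed lag, as limb_events.
make_onset_events <- function(paw, t_start, period, n, lag = 0, duty = 0.6,
                              t_end = NULL) {
  r <- t_start + lag * period + period * (seq_len(n) - 1)
  g <- r + (1 - duty) * period
  if (is.null(t_end)) t_end <- max(g) + period
  limb_events(paw, r, g, 0, t_end)
}

small_cohort_cfg <- function(...) {
  defaults <- list(n_mice = 3, sessions_per_mouse = 1, climbs_per_session = 3,
                   duty_d0 = 0.6, duty_speed_coupling = 0, idle_prob = 0,
                   slip_rate = 0, dropout_prob = 0, cycle_skip_prob = 0,
                   seed = 42)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
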