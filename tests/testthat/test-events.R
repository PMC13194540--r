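test_that("smooth_and_differentiate matches analytic derivatives", {
  fr <- 200
  # constant position: zero speed everywhere
  expect_equal(smooth_and_differentiate(rep(3, 100), fr, 5), rep(0, 100))

  # linear ramp, 5 cm over 1 s: exactly 5 cm/s in the interior
  y <- seq(0, 5, length.out = fr + 1)
  v <- smooth_and_differentiate(y, fr, 5)
  expect_equal(v[10:190], rep(5, 181), tolerance = 1e-9)

  # sine: the central difference alone attenuates the peak speed 2*pi*f*A
  # by sin(x)/x with x = 2*pi*f/fr, under 2% up to f = fr/20
  f <- fr / 20; A <- 1.5
  t <- (0:999) / fr
  y <- A * sin(2 * pi * f * t)
  v <- smooth_and_differentiate(y, fr, 1)
  expect_equal(max(abs(v)), 2 * pi * f * A, tolerance = 0.02)

  expect_error(smooth_and_differentiate(1:3, fr, 5), "shorter than window")
  expect_error(smooth_and_differentiate(1:50, fr, 4), "window_frames")
})

test_that("detect_events reproduces hand-enumerated square-wave crossings", {
  fr <- 200; dt <- 1 / fr
  # 0.25 s low / 0.25 s high, 4 cycles; enter 2, exit 1
  phase <- rep(c(0, 5), each = 50)
  sp <- rep(phase, 4)
  t <- (seq_along(sp) - 1) * dt
  ev <- detect_events(sp, t, enter_thresh = 2, exit_thresh = 1,
                      min_event_s = 0.025)
  # rising edges at samples 50->51, 150->151, ...: onset = last low sample
  expect_equal(ev$reach_onsets_s, t[c(50, 150, 250, 350)], tolerance = 1e-9)
  # falling edges: grasp = first low sample after the high run
  expect_equal(ev$grasp_onsets_s, t[c(101, 201, 301)], tolerance = 1e-9)
})

test_that("degenerate and sub-threshold traces are handled", {
  fr <- 200
  t <- (0:199) / fr
  ev <- detect_events(rep(0, 200), t)
  expect_length(ev$reach_onsets_s, 0)
  expect_equal(nrow(ev$grasp_intervals), 1L)
  expect_equal(ev$grasp_intervals$start_s, t[1])
  expect_equal(ev$grasp_intervals$end_s, t[200])

  # a 2-frame blip above threshold is merged away at min_event_s = 0.025
  sp <- rep(0, 200); sp[100:101] <- 5
  ev2 <- detect_events(sp, t, min_event_s = 0.025)
  expect_length(ev2$reach_onsets_s, 0)
})

test_that("slips are maximal sub-threshold runs with a strict boundary", {
  t <- (0:99) / 200
  expect_equal(detect_slips(rep(2, 100), t)$count, 0L)

  vy <- rep(0, 100); vy[40:44] <- -15
  s <- detect_slips(vy, t)
  expect_equal(s$count, 1L)
  expect_equal(s$times_s, t[40])

  vy2 <- rep(0, 100); vy2[40:44] <- -9.9
  expect_equal(detect_slips(vy2, t)$count, 0L)

  expect_equal(detect_slips(numeric(), numeric())$count, 0L)
})

test_that("slip count is monotone in the threshold", {
  set.seed(21)
  t <- (0:999) / 200
  vy <- rnorm(1000, -2, 6)
  counts <- vapply(c(-5, -8, -10, -15, -20),
                   function(th) detect_slips(vy, t, th)$count, 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("body speed integrates the tail-base path", {
  tr <- make_linear_track(n = 600, v = 5)
  bs <- body_speed(tr, window_s = 0.5)
  expect_equal(bs[50:550], rep(5, 501), tolerance = 1e-6)

  tr0 <- make_linear_track(n = 600, v = 0)
  expect_equal(max(abs(body_speed(tr0, 0.5))), 0, tolerance = 1e-9)

  # sawtooth path: path-length speed exceeds net-displacement speed
  n <- 600; t <- (0:(n - 1)) / 200
  y <- 2 + t * 2 + 0.5 * abs((t * 4) %% 2 - 1)
  mk <- function(dy) list(x = rep(10, n), y = y + dy, conf = rep(1, n))
  tr2 <- pose_track(t, list(nose = mk(5), tail_base = mk(0), rf = mk(3),
                            lf = mk(3), rh = mk(-2), lh = mk(-2)))
  bs2 <- body_speed(tr2, 0.5)
  net <- (y[n] - y[1]) / (t[n] - t[1])
  expect_gt(mean(bs2[100:500]), net)

  expect_error(body_speed(tr, window_s = 10), "window longer")
})

test_that("trial speed over the 20-cm band handles pauses and descents", {
  tr <- make_linear_track(n = 1200, v = 5)  # climbs 2 -> 32 cm
  ts <- trial_speed_20cm(tr, band_bottom_cm = 5)
  expect_false(ts$excluded)
  expect_equal(ts$speed_cm_s, 5, tolerance = 0.01)

  # 1-s pause inside the band at 10 cm/s elsewhere: 20 / (2 + 1)
  fr <- 200
  v_prof <- c(rep(10, 1.0 * fr), rep(0, 1.0 * fr), rep(10, 2.2 * fr))
  y <- 2 + cumsum(v_prof) / fr
  n <- length(y); t <- (0:(n - 1)) / fr
  mk <- function(dy) list(x = rep(10, n), y = y + dy, conf = rep(1, n))
  tr2 <- pose_track(t, list(nose = mk(5), tail_base = mk(0), rf = mk(3),
                            lf = mk(3), rh = mk(-2), lh = mk(-2)))
  ts2 <- trial_speed_20cm(tr2, band_bottom_cm = 5)
  expect_equal(ts2$speed_cm_s, 20 / 3, tolerance = 0.05)

  # descent-only trial is flagged, not an error
  n <- 400; t <- (0:(n - 1)) / fr
  y <- 30 - 5 * t
  mk <- function(dy) list(x = rep(10, n), y = y + dy, conf = rep(1, n))
  tr3 <- pose_track(t, list(nose = mk(5), tail_base = mk(0), rf = mk(3),
                            lf = mk(3), rh = mk(-2), lh = mk(-2)))
  expect_true(trial_speed_20cm(tr3, band_bottom_cm = 5)$excluded)
})

test_that("stride windows tile the grasp span", {
  ev <- limb_events("rf", reach_onsets_s = c(1.2, 1.8, 2.4),
                    grasp_onsets_s = c(1.0, 1.5, 2.1),
                    trial_start_s = 0, trial_end_s = 3)
  sw <- stride_windows(ev)
  expect_equal(sw$start_s, c(1.0, 1.5))
  expect_equal(sw$end_s, c(1.5, 2.1))
  # tiling: contiguous, non-overlapping
  expect_equal(sw$start_s[-1], sw$end_s[-nrow(sw)])

  ev1 <- limb_events("rf", numeric(), 1.0, 0, 3)
  expect_equal(nrow(stride_windows(ev1)), 0L)
})

test_that("event series enforce reach/grasp alternation", {
  expect_error(limb_events("rf", c(1, 1.5), c(2, 2.5), 0, 3),
               "alternate")
  ev <- limb_events("rf", c(0.5, 1.5), c(1.0, 2.0), 0, 3)
  # between any two reach onsets there is exactly one grasp onset
  r <- ev$reach_onsets_s; g <- ev$grasp_onsets_s
  for (k in seq_len(length(r) - 1))
    expect_equal(sum(g > r[k] & g < r[k + 1]), 1L)
})

test_that("segmentation recovers simulated onsets within 2 frames (sigma <= 0.05)", {
  set.seed(22)
  for (sig in c(0.03, 0.05)) {
    errs <- c()
    for (rep in 1:3) {
      tr <- simulate_trial(small_cohort_cfg(noise_sd_cm = sig))
      ev <- segment_track(tr$track)
      for (p in c("rf", "lf", "rh", "lh")) {
        tru <- tr$truth$events[[p]]$reach_onsets_s
        tru <- tru[tru > 0.3]
        det <- ev[[p]]$reach_onsets_s
        if (!length(det)) next
        errs <- c(errs, vapply(tru, function(x) min(abs(det - x)) * 200, 1.0))
      }
    }
    expect_lt(median(errs), 2)
  }
})
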