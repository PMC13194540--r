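make_gait_fixture <- function() {
  # rf grasps at y = 10 (t = 1.0) and y = 13 (t = 2.0); reach from t = 1.6;
  # lf holds at y = 8, x offset 3 cm
  n <- 600; fr <- 200
  t <- (0:(n - 1)) / fr
  rf_y <- ifelse(t < 1.6, 10, ifelse(t < 2.0, 10 + (t - 1.6) / 0.4 * 3, 13))
  mk <- function(x0, y) list(x = rep(x0, n), y = y, conf = rep(1, n))
  track <- pose_track(
    t,
    list(nose = mk(11, 20 + t), tail_base = mk(11, 12 + 2 * t),
         rf = mk(12, rf_y), lf = mk(9, rep(8, n)),
         rh = mk(13, rep(5, n)), lh = mk(8, rep(5, n))),
    meta = list(mouse_id = "m1", session_id = "s1", trial_id = "t1"))
  events <- list(
    rf = limb_events("rf", reach_onsets_s = 1.6, grasp_onsets_s = c(1.0, 2.0),
                     trial_start_s = 0, trial_end_s = t[n]),
    lf = limb_events("lf", numeric(), 0.5, 0, t[n]),
    rh = limb_events("rh", numeric(), 0.5, 0, t[n]),
    lh = limb_events("lh", numeric(), 0.5, 0, t[n]))
  list(track = track, events = events)
}

test_that("stride metrics match hand-computed values", {
  fx <- make_gait_fixture()
  st <- compute_stride_metrics(fx$track, fx$events)
  expect_equal(nrow(st), 1L)
  expect_equal(st$stride_length_cm, 3, tolerance = 1e-6)
  # grasp 1.0 -> 1.6 (0.6 s), reach 1.6 -> 2.0 (0.4 s): duty 0.6
  expect_equal(st$grasp_duration_s, 0.6, tolerance = 1e-6)
  expect_equal(st$reach_duration_s, 0.4, tolerance = 1e-6)
  expect_equal(st$duty_factor, 0.6, tolerance = 1e-6)
  # homologue comparisons at the stride-opening grasp (t = 1.0):
  expect_equal(st$step_length_cm, 2, tolerance = 1e-6)   # |10 - 8|
  expect_equal(st$step_width_cm, 3, tolerance = 1e-6)    # |12 - 9|
  expect_equal(st$reach_length_cm, 3, tolerance = 0.02)  # straight 3-cm reach
  # body speed over the stride: tail base at 2 cm/s
  expect_equal(st$body_speed_cm_s, 2, tolerance = 0.01)
  expect_equal(st$limb_class, "fore")
})

test_that("duty-factor invariant holds on simulated strides", {
  set.seed(31)
  tr <- simulate_trial(small_cohort_cfg())
  st <- compute_stride_metrics(tr$track, segment_track(tr$track))
  expect_true(all(st$duty_factor >= 0 & st$duty_factor <= 1))
  expect_equal(st$duty_factor,
               st$grasp_duration_s / (st$grasp_duration_s + st$reach_duration_s),
               tolerance = 1e-9)
  expect_true(all(st$stride_length_cm >= 0))
})

test_that("speed binning pools paws within class and flags sparse bins", {
  rec <- expand.grid(mouse_id = sprintf("m%d", 1:9), paw = c("rf", "lf"),
                     stringsAsFactors = FALSE)
  rec$limb_class <- "fore"
  rec$body_speed_cm_s <- ifelse(rec$mouse_id == "m1", 0.5, 1.5)
  for (col in c("reach_length_cm", "step_length_cm", "stride_length_cm",
                "step_width_cm", "reach_duration_s", "grasp_duration_s"))
    rec[[col]] <- 1
  rec$duty_factor <- ifelse(rec$paw == "rf", 0.4, 0.6)
  b <- bin_by_speed(rec, bin_width = 1.6, min_mice = 8)
  # speeds 0.5 and 1.5 share bin [0, 1.6)
  expect_equal(unique(b$speed_bin), 0)
  # left/right pooled: per-mouse class mean of 0.4 and 0.6 is 0.5
  expect_equal(b$duty_factor, rep(0.5, 9), tolerance = 1e-9)
  expect_true(all(b$inferential))  # 9 mice >= 8

  b7 <- bin_by_speed(rec[rec$mouse_id %in% sprintf("m%d", 1:7), ],
                     min_mice = 8)
  expect_false(any(b7$inferential))
})

test_that("feature-speed correlations use the right estimator per shape", {
  set.seed(32)
  mk <- function(mouse, n = 500) {
    v <- runif(n, 0.7, 13)
    data.frame(mouse_id = mouse, limb_class = "fore", body_speed_cm_s = v,
               prop = 2 * v, indep = rnorm(n), mono = exp(v / 4),
               stringsAsFactors = FALSE)
  }
  rec <- rbind(mk("m1"), mk("m2"), mk("m3"))
  expect_equal(unname(feature_speed_correlation(rec, "prop")$per_mouse),
               rep(1, 3), tolerance = 1e-9)
  # independence: small coefficients under simulation
  expect_lt(abs(feature_speed_correlation(rec, "indep")$median), 0.1)
  # monotone nonlinear: Spearman exactly 1, Pearson below 1
  sp <- feature_speed_correlation(rec, "mono", method = "spearman")
  pe <- feature_speed_correlation(rec, "mono", method = "pearson")
  expect_equal(unname(sp$per_mouse), rep(1, 3), tolerance = 1e-9)
  expect_true(all(pe$per_mouse < 1))

  rec$mouse_id[1:2] <- "tiny"
  expect_warning(feature_speed_correlation(rec[c(1:2, 501:1000), ], "prop"),
                 "dropped")
})

test_that("speed-coupled duty factor yields negative per-mouse correlations", {
  set.seed(33)
  cfg <- sim_config(n_mice = 3, sessions_per_mouse = 1, climbs_per_session = 4,
                    duty_d0 = 0.75, duty_speed_coupling = 0.02, idle_prob = 0,
                    slip_rate = 0, dropout_prob = 0, seed = 77)
  coh <- simulate_cohort(cfg)
  res <- run_standard(coh)
  fc <- feature_speed_correlation(res$stride_records, "duty_factor")
  expect_true(all(fc$per_mouse < 0))
})
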