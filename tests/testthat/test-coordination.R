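# frame-wise boolean oracle for the Jaccard index on a fine grid
jaccard_grid_oracle <- function(a, b, dt = 1e-3, t_max = NULL) {
  if (is.null(t_max)) t_max <- max(c(a$end_s, b$end_s, 1))
  g <- seq(0, t_max, by = dt)
  inA <- rep(FALSE, length(g)); inB <- rep(FALSE, length(g))
  for (k in seq_len(nrow(a))) inA <- inA | (g >= a$start_s[k] & g < a$end_s[k])
  for (k in seq_len(nrow(b))) inB <- inB | (g >= b$start_s[k] & g < b$end_s[k])
  u <- sum(inA | inB)
  if (u == 0) 0 else sum(inA & inB) / u
}

iv <- function(s, e) data.frame(start_s = s, end_s = e)

test_that("the phase-offset formula reproduces hand-computed values", {
  ref <- limb_events("rf", c(0, 1), c(0.6, 1.6), 0, 2)
  tgt <- limb_events("lf", 0.5, 1.1, 0, 2)
  ph <- directed_phase_offsets(ref, tgt)
  expect_equal(ph$phi, 0.5)
  expect_equal(ph$phi_deg, 180)

  # coincident onsets: phi = 0 (the target onset at t0 is inside [t0, t1))
  tgt0 <- limb_events("lf", c(0, 1), c(0.6, 1.6), 0, 2)
  ph0 <- directed_phase_offsets(ref, tgt0)  # one reference period [0, 1)
  expect_equal(ph0$phi, 0)

  # printed-formula arithmetic: t0 = 2.0, t1 = 2.8, ts = 2.2 -> 0.25
  ref2 <- limb_events("rf", c(2.0, 2.8), c(2.5, 3.2), 0, 4)
  tgt2 <- limb_events("lf", 2.2, 2.6, 0, 4)
  expect_equal(directed_phase_offsets(ref2, tgt2)$phi, 0.25)

  # fewer than two reference onsets: empty
  expect_equal(nrow(directed_phase_offsets(tgt2, ref2)), 0L)
})

test_that("multiple target onsets in one period use the first", {
  ref <- limb_events("rf", c(0, 1), c(0.7, 1.7), 0, 2)
  tgt <- limb_events("lf", c(0.2, 0.6), c(0.4, 0.9), 0, 2)
  ph <- directed_phase_offsets(ref, tgt)
  expect_equal(ph$phi, 0.2)
})

test_that("bidirectional samples are symmetric for alternating and lagged trains", {
  # perfect alternation: both directions concentrate at 0.5
  A <- make_onset_events("rf", 0, 1, 10, lag = 0)
  B <- make_onset_events("lf", 0, 1, 10, lag = 0.5)
  bi <- bidirectional_pair_samples(A, B, pair = "FF")
  expect_true(all(abs(bi$phi - 0.5) < 1e-9))
  expect_setequal(unique(bi$reference_paw), c("rf", "lf"))

  # synchrony: both directions concentrate near 0
  B0 <- make_onset_events("lf", 0, 1, 10, lag = 0)
  bi0 <- bidirectional_pair_samples(A, B0, pair = "FF")
  expect_true(all(bi0$phi < 1e-9))

  # B lagging A by 0.25: A-referenced 0.25, B-referenced 0.75
  B25 <- make_onset_events("lf", 0, 1, 10, lag = 0.25)
  bi25 <- bidirectional_pair_samples(A, B25, pair = "FF")
  expect_true(all(abs(bi25$phi[bi25$reference_paw == "rf"] - 0.25) < 1e-9))
  expect_true(all(abs(bi25$phi[bi25$reference_paw == "lf"] - 0.75) < 1e-9))
})

test_that("lift-off percentile filter uses the pooled group percentile", {
  s <- data.frame(phi = rep(0.5, 10), phi_deg = 180,
                  liftoff_duration_s = c(rep(1, 9), 100))
  out <- liftoff_percentile_filter(s, 90)
  expect_equal(nrow(out), 9L)
  expect_true(all(out$liftoff_duration_s == 1))

  all_eq <- data.frame(phi = rep(0.1, 8), phi_deg = 36,
                       liftoff_duration_s = rep(2, 8))
  expect_equal(nrow(liftoff_percentile_filter(all_eq, 90)), 8L)
  expect_equal(nrow(liftoff_percentile_filter(s, 100)), 10L)
  expect_equal(nrow(liftoff_percentile_filter(s[0, ], 90)), 0L)
})

test_that("jaccard_index matches exact arithmetic and the grid oracle", {
  a <- iv(c(0, 4), c(2, 6)); b <- iv(1, 3)
  expect_equal(jaccard_index(a, b), 0.2, tolerance = 1e-12)
  expect_equal(jaccard_index(a, a), 1.0)
  expect_equal(jaccard_index(iv(0, 1), iv(2, 3)), 0)
  expect_equal(jaccard_index(iv(numeric(), numeric()),
                             iv(numeric(), numeric())), 0)
  expect_error(jaccard_index(iv(c(0, 1), c(2, 3)), b), "overlapping")

  set.seed(41)
  for (k in 1:25) {
    na <- sample(1:5, 1); nb <- sample(1:5, 1)
    sa <- sort(runif(2 * na)); sb <- sort(runif(2 * nb))
    A <- iv(sa[seq(1, 2 * na, 2)], sa[seq(2, 2 * na, 2)])
    B <- iv(sb[seq(1, 2 * nb, 2)], sb[seq(2, 2 * nb, 2)])
    expect_equal(jaccard_index(A, B), jaccard_index(B, A), tolerance = 1e-12)
    expect_lt(abs(jaccard_index(A, B) - jaccard_grid_oracle(A, B, 1e-4)),
              2e-3)
  }

  # grid-aligned intervals agree with the boolean oracle to 1e-9
  A <- iv(c(0.10, 0.40), c(0.25, 0.70)); B <- iv(0.20, 0.55)
  expect_lt(abs(jaccard_index(A, B) - jaccard_grid_oracle(A, B, 5e-3)), 1e-9)
})

test_that("speed-binned phase summaries use half-open 2.05-cm/s bins", {
  expect_equal((8.9 - 0.7) / 4, 2.05)
  s <- data.frame(pair = "FF", phi = 0.5, phi_deg = 180,
                  body_speed_cm_s = c(0.7, 2.74, 2.76, 8.89, 8.9, 0.5),
                  mouse_id = "m1", liftoff_duration_s = 1,
                  stringsAsFactors = FALSE)
  out <- phase_by_speed_bins(s)
  pm <- out$per_mouse
  # 0.7 and 2.74 -> bin 0; 2.76 -> bin 1; 8.89 -> bin 3; 8.9, 0.5 excluded
  expect_equal(sort(unique(pm$speed_bin)), c(0, 1, 3))
  expect_equal(sum(pm$n), 4)

  # anti-phase limbs at uniform speeds: all bins mean ~ 180 deg
  set.seed(42)
  n <- 400
  sim <- data.frame(pair = "FF",
                    phi_deg = wrap_deg(180 + rnorm(n, 0, 20)),
                    body_speed_cm_s = runif(n, 0.7, 8.9),
                    mouse_id = sample(c("m1", "m2", "m3"), n, TRUE),
                    liftoff_duration_s = 1, stringsAsFactors = FALSE)
  sim$phi <- sim$phi_deg / 360
  g <- phase_by_speed_bins(sim)$group
  expect_equal(nrow(g), 4L)
  expect_true(all(abs(g$mean_deg - 180) < 10))
})

test_that("trial tables carry all six pairs", {
  set.seed(43)
  tr <- simulate_trial(small_cohort_cfg())
  ev <- segment_track(tr$track)
  ph <- trial_phase_samples(ev, tr$track)
  ov <- trial_pair_overlaps(ev, tr$track$meta)
  expect_setequal(unique(ph$pair),
                  c("FF", "HH", "DIAG_RFLH", "DIAG_LFRH", "LAT_R", "LAT_L"))
  expect_equal(nrow(ov), 6L)
  expect_true(all(ov$jaccard >= 0 & ov$jaccard <= 1))
  expect_true(all(ph$phi >= 0 & ph$phi < 1))
  expect_true(all(ph$liftoff_duration_s > 0))
})
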