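test_that("circ_mean matches direct vector sums", {
  s <- circ_mean(c(0, 0))
  expect_equal(s$mean_direction_deg, 0)
  expect_equal(s$resultant_r, 1)

  expect_lt(circ_mean(c(0, 180))$resultant_r, 1e-12)

  s <- circ_mean(c(0, 90))
  expect_equal(s$mean_direction_deg, 45, tolerance = 1e-9)
  expect_equal(s$resultant_r, cos(pi / 4), tolerance = 1e-9)

  expect_error(circ_mean(numeric()), "at least one")
})

test_that("Rayleigh test behaves at the uniform and degenerate extremes", {
  uniform8 <- seq(0, 315, by = 45)
  rt <- rayleigh_test(uniform8)
  expect_lt(rt$z, 1e-20)
  expect_gt(rt$p, 0.99)

  # ten identical angles: p = exp(sqrt(1 + 4n) - (1 + 2n)) at r = 1
  rt <- rayleigh_test(rep(77, 10))
  expect_lt(rt$p, 0.001)
  expect_equal(rt$p, exp(sqrt(41) - 21), tolerance = 1e-9)

  expect_warning(rayleigh_test(c(10, 20)), "n < 3")
})

test_that("Rayleigh p agrees with a Monte-Carlo null (n = 10, r = 0.5)", {
  # independent oracle: distribution of r under uniformity
  set.seed(101)
  n <- 10; ndraw <- 2e4
  th <- matrix(runif(ndraw * n, 0, 2 * pi), ndraw)
  r_null <- sqrt(rowSums(sin(th))^2 + rowSums(cos(th))^2) / n
  p_mc <- mean(r_null >= 0.5)
  # analytic approximation at the same r
  R <- n * 0.5
  p_an <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  expect_lt(abs(p_an - p_mc), 0.01)
})

test_that("rotation equivariance holds for summaries and tests", {
  set.seed(7)
  for (shift in c(30, 123.4, 270)) {
    a <- runif(40, 0, 360)
    s0 <- circ_mean(a); s1 <- circ_mean(a + shift)
    expect_equal(wrap_deg(s1$mean_direction_deg - s0$mean_direction_deg),
                 wrap_deg(shift), tolerance = 1e-6)
    expect_equal(s1$resultant_r, s0$resultant_r, tolerance = 1e-12)
    expect_equal(s1$rayleigh_p, s0$rayleigh_p, tolerance = 1e-12)
    # shifting both groups leaves the Watson-Williams test invariant
    g <- list(rnorm(15, 120, 8), rnorm(15, 150, 8))
    ws0 <- watson_williams(g)
    ws1 <- watson_williams(lapply(g, `+`, shift))
    expect_equal(ws1$F, ws0$F, tolerance = 1e-9)
    expect_equal(ws1$p, ws0$p, tolerance = 1e-9)
  }
})

test_that("resultant length r stays in [0, 1] and hits 1 only when identical", {
  set.seed(8)
  for (k in 1:20) {
    a <- runif(sample(3:50, 1), 0, 360)
    r <- circ_mean(a)$resultant_r
    expect_gte(r, 0); expect_lte(r, 1 + 1e-12)
  }
  expect_equal(circ_mean(rep(12.3, 7))$resultant_r, 1, tolerance = 1e-12)
  expect_lt(circ_mean(c(10, 10, 10.5))$resultant_r, 1)
})

test_that("Watson-Williams separates shifted concentrated samples", {
  set.seed(9)
  kappa_sd <- sqrt(1 / 50) * 180 / pi  # ~ von Mises kappa = 50
  a <- rnorm(10, 45, kappa_sd); b <- rnorm(10, 135, kappa_sd)
  ww <- watson_williams(list(a, b))
  expect_lt(ww$p, 0.001)

  same <- rnorm(12, 200, 5)
  ww0 <- watson_williams(list(same, same))
  expect_lt(ww0$F, 1e-9)
  expect_gt(ww0$p, 0.9)

  expect_error(watson_williams(list(a)), ">= 2 groups")
  expect_error(watson_williams(list(a, numeric())), "empty group")
  expect_warning(watson_williams(list(runif(30, 0, 360), runif(30, 0, 360))),
                 "concentrated")
})

test_that("Watson-Williams p agrees with a permutation oracle", {
  set.seed(10)
  a <- rnorm(10, 80, 15); b <- rnorm(10, 110, 15)
  ww <- suppressWarnings(watson_williams(list(a, b)))
  pooled <- c(a, b)
  ww_F <- function(g1, g2) suppressWarnings(watson_williams(list(g1, g2))$F)
  obs <- ww$F
  nperm <- 2000
  cnt <- 0
  for (i in seq_len(nperm)) {
    idx <- sample(20, 10)
    if (ww_F(pooled[idx], pooled[-idx]) >= obs) cnt <- cnt + 1
  }
  expect_equal(ww$p, cnt / nperm, tolerance = 0.03)
})

test_that("circular-linear regression recovers constant and sloped phase", {
  set.seed(11)
  v <- runif(200, 0.7, 12)
  th <- rep(180, 200) + rnorm(200, 0, 8)
  fit <- circ_linear_regression(th, v)
  expect_equal(fit$intercept_deg, 180, tolerance = 3)
  expect_lt(abs(fit$slope_deg_per_unit), 0.6)

  # slope recovery: 4 deg per unit with von-Mises-like noise (kappa ~ 20)
  v <- runif(300, 0, 10)
  th <- 90 + 4 * v + rnorm(300, 0, sqrt(1 / 20) * 180 / pi)
  fit <- circ_linear_regression(th, v)
  expect_equal(fit$slope_deg_per_unit, 4, tolerance = 0.5)

  expect_error(circ_linear_regression(th, rep(3, 300)), "constant covariate")
})

test_that("flat-phase cohorts give a null slope t test", {
  set.seed(12)
  slopes <- vapply(1:10, function(i) {
    v <- runif(150, 0.7, 9)
    th <- 180 + rnorm(150, 0, 20)
    circ_linear_regression(th, v)$slope_deg_per_unit
  }, 1.0)
  tt <- slope_t_test(slopes)
  expect_gt(tt$p, 0.05)
  expect_error(slope_t_test(1), ">= 2")
})
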