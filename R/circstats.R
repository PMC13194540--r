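#' Circular statistics for interlimb phase data
#'
#' Phase offsets between limb pairs live on the circle: 0 and 360 degrees are
#' the same (in-phase) state and 180 degrees is anti-phase. These helpers
#' provide the descriptive summaries and tests used throughout the package:
#' circular mean and resultant length, the Rayleigh test of non-uniformity,
#' the Watson-Williams comparison of mean directions, and circular-linear
#' regression of phase on body speed.
#'
#' @name circstats
#' @keywords internal
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles in degrees to [0, 360)
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped to `[0, 360)`.
#' @export
wrap_deg <- function(x) ((x %% 360) + 360) %% 360

#' Circular mean, resultant length and Rayleigh statistics
#'
#' Computes the mean direction `atan2(sum(sin), sum(cos))`, the mean resultant
#' length `r = |sum(exp(i theta))| / n`, the circular standard deviation
#' `sqrt(-2 log r)` and the Rayleigh test of uniformity with `z = n r^2` and
#' `p = exp(sqrt(1 + 4n + 4(n^2 - R^2)) - (1 + 2n))` where `R = n r`.
#'
#' @param angles_deg numeric vector of angles in degrees.
#' @return an object of class `circ_summary`: a list with `n`,
#'   `mean_direction_deg` in `[0, 360)`, `resultant_r`, `circ_sd_deg`,
#'   `rayleigh_z` and `rayleigh_p`.
#' @examples
#' circ_mean(c(0, 90))   # mean 45 degrees, r = cos(45 deg)
#' @export
circ_mean <- function(angles_deg) {
  angles_deg <- angles_deg[is.finite(angles_deg)]
  n <- length(angles_deg)
  if (n == 0L) stop("circ_mean() requires at least one finite angle")
  th <- deg2rad(angles_deg)
  S <- sum(sin(th)); C <- sum(cos(th))
  r <- sqrt(S^2 + C^2) / n
  mu <- wrap_deg(rad2deg(atan2(S, C)))
  sd_deg <- if (r > 0) rad2deg(sqrt(-2 * log(min(r, 1)))) else Inf
  R <- n * r
  z <- n * r^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  structure(
    list(n = n, mean_direction_deg = mu, resultant_r = r,
         circ_sd_deg = sd_deg, rayleigh_z = z,
         rayleigh_p = min(max(p, 0), 1)),
    class = "circ_summary"
  )
}

#' @export
print.circ_summary <- function(x, ...) {
  cat(sprintf(
    "Circular summary: n = %d, mean = %.2f deg, r = %.3f, Rayleigh z = %.3f, p = %.3g\n",
    x$n, x$mean_direction_deg, x$resultant_r, x$rayleigh_z, x$rayleigh_p))
  invisible(x)
}

#' Rayleigh test of circular uniformity
#'
#' @param angles_deg numeric vector of angles in degrees.
#' @return list with `z`, `p` and `n`; warns when `n < 3`, where the
#'   approximation is unreliable.
#' @export
rayleigh_test <- function(angles_deg) {
  s <- circ_mean(angles_deg)
  if (s$n < 3) warning("rayleigh_test(): n < 3, p value unreliable")
  list(z = s$rayleigh_z, p = s$rayleigh_p, n = s$n)
}

## Best-fitting von Mises concentration for a given mean resultant length
## (standard three-branch approximation to the inverse of A(kappa)).
kappa_from_r <- function(r) {
  if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
}

#' Watson-Williams test for equality of circular mean directions
#'
#' Circular one-way ANOVA for two or more groups of angles. Assumes the
#' groups are von Mises with a common, reasonably large concentration; a
#' warning is issued when the pooled mean resultant length drops below 0.45,
#' where the F approximation degrades (the test is still computed).
#'
#' @param groups list of numeric vectors of angles in degrees (>= 2 groups,
#'   each non-empty; the concentrated-data assumption wants each n >= 3).
#' @return list with `F`, `p`, `df1`, `df2`, `kappa` and the per-group
#'   summaries.
#' @export
watson_williams <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("watson_williams() requires a list of >= 2 groups")
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (any(vapply(groups, length, 1L) == 0L))
    stop("watson_williams(): empty group")
  if (any(vapply(groups, length, 1L) < 3L))
    warning("watson_williams(): group with n < 3; result unreliable")
  k <- length(groups)
  ns <- vapply(groups, length, 1L)
  N <- sum(ns)
  th <- lapply(groups, deg2rad)
  Ri <- vapply(th, function(x) sqrt(sum(sin(x))^2 + sum(cos(x))^2), 1.0)
  all_th <- unlist(th)
  R <- sqrt(sum(sin(all_th))^2 + sum(cos(all_th))^2)
  rw <- sum(Ri) / N
  if (rw < 0.45)
    warning("watson_williams(): pooled resultant length < 0.45; the F approximation assumes concentrated data")
  kap <- kappa_from_r(rw)
  g <- 1 + 3 / (8 * kap)
  num <- (sum(Ri) - R) / (k - 1)
  den <- (N - sum(Ri)) / (N - k)
  Fstat <- if (den <= 0) Inf else g * num / den
  p <- stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE)
  list(F = Fstat, p = p, df1 = k - 1, df2 = N - k, kappa = kap,
       group_r = Ri / ns, pooled_r = R / N)
}

## Profile log-likelihood machinery for the Fisher-Lee circular-linear model:
## theta_i ~ vonMises(mu + 2*atan(beta * v_i), kappa). For fixed beta the
## optimal mu is the circular mean of the residual angles, and the profiled
## objective is the resultant length of those residuals.
cl_resultant <- function(beta, th, v) {
  resid <- th - 2 * atan(beta * v)
  sqrt(sum(sin(resid))^2 + sum(cos(resid))^2)
}

#' Circular-linear regression of phase on a linear covariate
#'
#' Fits the Fisher-Lee model `theta_i ~ mu + g(beta * v_i)` with link
#' `g(x) = 2 atan(x)` under von Mises errors, by maximising the profile
#' likelihood over the slope. The reported `slope_deg_per_unit` is the
#' small-covariate slope `2 * beta` converted to degrees, i.e. the local rate
#' of phase change per unit of the covariate near `v = 0`; the raw link-scale
#' coefficient `beta` is returned alongside. Standard error comes from the
#' curvature of the profile log-likelihood at the optimum.
#'
#' @param angles_deg angles in degrees.
#' @param x numeric covariate (e.g. body speed in cm/s), same length.
#' @param beta_range search interval for the link-scale slope. The default
#'   allows local slopes up to ~57 degrees per covariate unit; much wider
#'   ranges admit a degenerate saturated solution (`2 atan` pinned at
#'   +/-180 degrees) that perfectly "fits" any data modulo 360.
#' @return object of class `circ_lin_fit`: list with `intercept_deg` (wrapped
#'   to `[0, 360)`), `slope_deg_per_unit`, `slope_se` (same units), `beta`,
#'   `kappa`, `n`.
#' @export
circ_linear_regression <- function(angles_deg, x, beta_range = c(-0.5, 0.5)) {
  keep <- is.finite(angles_deg) & is.finite(x)
  angles_deg <- angles_deg[keep]; x <- x[keep]
  n <- length(angles_deg)
  if (n < 4L) stop("circ_linear_regression() requires >= 4 observations")
  if (stats::sd(x) == 0) stop("circ_linear_regression(): constant covariate, slope undefined")
  th <- deg2rad(angles_deg)
  ## centre the covariate so the intercept is the phase at the mean covariate
  ## and the atan link bends symmetrically around it
  x0 <- mean(x)
  v <- x - x0
  opt <- stats::optimize(function(b) cl_resultant(b, th, v),
                         interval = beta_range, maximum = TRUE)
  beta <- opt$maximum
  R <- opt$objective
  r <- R / n
  kap <- kappa_from_r(min(r, 0.999999))
  resid <- th - 2 * atan(beta * v)
  mu <- atan2(sum(sin(resid)), sum(cos(resid)))
  ## profile log-likelihood l(beta) = kappa * R(beta); numeric curvature
  h <- max(1e-5, abs(beta) * 1e-3)
  d2 <- kap * (cl_resultant(beta + h, th, v) - 2 * R +
                 cl_resultant(beta - h, th, v)) / h^2
  se_beta <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  structure(
    list(intercept_deg = wrap_deg(rad2deg(mu)),
         slope_deg_per_unit = rad2deg(2 * beta),
         slope_se = rad2deg(2 * se_beta),
         beta = beta, kappa = kap, n = n, x_center = x0),
    class = "circ_lin_fit"
  )
}

#' @export
print.circ_lin_fit <- function(x, ...) {
  cat(sprintf(
    "Circular-linear fit: intercept = %.2f deg, slope = %.4f deg/unit (SE %.4f), kappa = %.2f, n = %d\n",
    x$intercept_deg, x$slope_deg_per_unit, x$slope_se, x$kappa, x$n))
  invisible(x)
}

#' One-sample t test of per-mouse circular-linear slopes against zero
#'
#' The group-level test of speed dependence: fit one circular-linear
#' regression per mouse, then test the slopes against zero.
#'
#' @param slopes numeric vector of per-mouse slopes.
#' @return list with `t`, `p`, `mean`, `sd`, `n`.
#' @export
slope_t_test <- function(slopes) {
  slopes <- slopes[is.finite(slopes)]
  if (length(slopes) < 2L) stop("slope_t_test() requires >= 2 slopes")
  tt <- stats::t.test(slopes, mu = 0)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean = mean(slopes), sd = stats::sd(slopes), n = length(slopes))
}
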