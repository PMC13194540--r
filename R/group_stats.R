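#' Mouse-level inferential statistics
#'
#' The mouse is the experimental unit: strides and phase samples are nested
#' within sessions within mice, so group inference uses linear mixed-effects
#' models with a random intercept per mouse (Jaccard pair/location models,
#' speed x limb gait models) or non-parametric session comparisons on
#' per-mouse means (Kruskal-Wallis with Wilcoxon / Mann-Whitney post hocs,
#' gated by a Shapiro-Wilk normality check).
#'
#' @name group_stats
#' @keywords internal
NULL

#' Fit a linear mixed-effects model with a random intercept per mouse
#'
#' REML fit of `response ~ fixed + (1 | mouse_id)` via lme4. P values for
#' fixed effects use a t statistic on the residual degrees of freedom
#' (n_obs - n fixed-effect parameters - n_mice), recorded in the output;
#' singular fits fall back to ordinary least squares with a warning.
#'
#' @param table data.frame with a `mouse_id` column.
#' @param response response column name.
#' @param fixed character vector of fixed-effect terms (e.g. `c("speed",
#'   "limb_class", "speed:limb_class")`).
#' @return object of class `lmm_result`: list with `fixed_effects`
#'   (data.frame: term, estimate, se, t, df, p), `random_intercept_sd`,
#'   `sigma`, `n_obs`, `n_mice`, `model` (the lme4 fit or lm fallback),
#'   `df_method`.
#' @export
lmm_fit <- function(table, response, fixed) {
  stopifnot(response %in% names(table), "mouse_id" %in% names(table))
  n_mice <- length(unique(table$mouse_id))
  if (n_mice < 2)
    stop("lmm_fit(): needs >= 2 mice to identify a random intercept")
  fml <- stats::as.formula(paste(response, "~", paste(fixed, collapse = " + "),
                                 "+ (1 | mouse_id)"))
  fit <- lme4::lmer(fml, data = table, REML = TRUE)
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    warning("lmm_fit(): singular random-effect fit; falling back to fixed-effects-only least squares")
    fml2 <- stats::as.formula(paste(response, "~", paste(fixed, collapse = " + ")))
    lmfit <- stats::lm(fml2, data = table)
    sm <- summary(lmfit)$coefficients
    fe <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                     t = sm[, 3], df = lmfit$df.residual, p = sm[, 4],
                     row.names = NULL, stringsAsFactors = FALSE)
    return(structure(list(fixed_effects = fe, random_intercept_sd = 0,
                          sigma = summary(lmfit)$sigma, n_obs = nrow(table),
                          n_mice = n_mice, model = lmfit,
                          df_method = "residual (lm fallback)"),
                     class = "lmm_result"))
  }
  co <- lme4::fixef(fit)
  vc <- as.matrix(stats::vcov(fit))
  se <- sqrt(diag(vc))
  df <- nrow(stats::model.frame(fit)) - length(co) - n_mice
  df <- max(df, 1)
  tval <- co / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  vcov_re <- as.data.frame(lme4::VarCorr(fit))
  ri_sd <- vcov_re$sdcor[vcov_re$grp == "mouse_id"][1]
  structure(list(
    fixed_effects = data.frame(term = names(co), estimate = unname(co),
                               se = unname(se), t = unname(tval), df = df,
                               p = unname(p), row.names = NULL,
                               stringsAsFactors = FALSE),
    random_intercept_sd = ri_sd,
    sigma = stats::sigma(fit), n_obs = nrow(stats::model.frame(fit)),
    n_mice = n_mice, model = fit, df_method = "residual"),
    class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("Mixed model (%d obs, %d mice, random-intercept SD %.4g):\n",
              x$n_obs, x$n_mice, x$random_intercept_sd))
  print(x$fixed_effects, digits = 4)
  invisible(x)
}

#' Limb contrasts per speed bin with Bonferroni adjustment
#'
#' Fits `response ~ limb_class * factor(speed_bin) + (1 | mouse_id)` on the
#' per-mouse binned table and evaluates the fore-vs-hind contrast of the
#' model's estimated marginal means within each speed bin. Raw p values are
#' Bonferroni-multiplied by the number of inferential bins (the contrast
#' family is one panel); bins with fewer contributing mice than the
#' inclusion rule are reported but flagged descriptive and excluded from
#' the adjustment family.
#'
#' @param binned output of [bin_by_speed()] (one row per mouse x bin x limb
#'   class).
#' @param response metric column to model.
#' @return data.frame with one row per speed bin: `estimate` (fore minus
#'   hind), `se`, `df`, `p_raw`, `p_adjusted`, `inferential`.
#' @export
pairwise_contrasts <- function(binned, response) {
  stopifnot(all(c("limb_class", "speed_bin", "mouse_id") %in% names(binned)))
  binned <- binned[is.finite(binned[[response]]), , drop = FALSE]
  ## only bins with both limb classes can be contrasted
  tab <- table(binned$speed_bin, binned$limb_class)
  bins <- as.integer(rownames(tab)[apply(tab > 0, 1, all)])
  binned <- binned[binned$speed_bin %in% bins, , drop = FALSE]
  binned$speed_bin_f <- factor(binned$speed_bin)
  binned$limb_class <- factor(binned$limb_class, levels = c("fore", "hind"))
  fit <- lmm_fit(binned, response, c("limb_class * speed_bin_f"))
  co <- fit$fixed_effects$estimate
  names(co) <- fit$fixed_effects$term
  V <- if (inherits(fit$model, "lm")) stats::vcov(fit$model)
       else as.matrix(stats::vcov(fit$model))
  lev <- levels(binned$speed_bin_f)
  infer <- vapply(lev, function(b) {
    sub <- binned[binned$speed_bin_f == b, ]
    all(tapply(sub$mouse_id, sub$limb_class,
               function(m) length(unique(m))) >= 1) &&
      isTRUE(all(sub$inferential))
  }, TRUE)
  n_fam <- max(sum(infer), 1)
  out <- lapply(seq_along(lev), function(j) {
    L <- setNames(numeric(length(co)), names(co))
    L["limb_classhind"] <- -1  # contrast: fore - hind at this bin
    if (j > 1) {
      nm <- paste0("limb_classhind:speed_bin_f", lev[j])
      if (nm %in% names(L)) L[nm] <- -1
    }
    est <- sum(L * co)
    se <- sqrt(drop(t(L) %*% V %*% L))
    df <- fit$fixed_effects$df[1]
    p <- 2 * stats::pt(abs(est / se), df, lower.tail = FALSE)
    data.frame(speed_bin = as.integer(lev[j]), estimate = est, se = se,
               df = df, p_raw = p,
               p_adjusted = if (infer[j]) min(p * n_fam, 1) else NA_real_,
               inferential = infer[j])
  })
  do.call(rbind, out)
}

#' Session-stability tests on per-mouse, per-session means
#'
#' A Shapiro-Wilk check on the session-centred residuals chooses the
#' branch: non-normal (or forced) data use Kruskal-Wallis across sessions
#' with post-hoc paired Wilcoxon signed-rank tests (Bonferroni adjusted)
#' run only when the omnibus test is significant; normal data use one-way
#' ANOVA with pairwise t tests.
#'
#' @param tab data.frame with `mouse_id`, `session_id`, `value`.
#' @param alpha omnibus significance gate for post hocs.
#' @return list with `normal` (Shapiro verdict), `test` (`"kruskal"` or
#'   `"anova"`), `statistic`, `p`, and `posthoc` (data.frame or NULL).
#' @export
session_tests <- function(tab, alpha = 0.05) {
  stopifnot(all(c("mouse_id", "session_id", "value") %in% names(tab)))
  sessions <- sort(unique(tab$session_id))
  if (length(sessions) < 3) stop("session_tests(): needs >= 3 sessions")
  resid <- unlist(lapply(split(tab$value, tab$session_id),
                         function(v) v - mean(v)))
  normal <- if (length(resid) >= 3 && stats::sd(resid) > 0)
    stats::shapiro.test(resid)$p.value > 0.05 else FALSE
  if (stats::sd(tab$value) == 0) {
    ## all values identical: H = 0, nothing to test
    return(list(normal = TRUE, test = "kruskal", statistic = 0, p = 1,
                posthoc = NULL))
  }
  if (normal) {
    fit <- stats::aov(value ~ factor(session_id), data = tab)
    sm <- summary(fit)[[1]]
    stat <- sm[["F value"]][1]; p <- sm[["Pr(>F)"]][1]
    test <- "anova"
  } else {
    kw <- stats::kruskal.test(tab$value, factor(tab$session_id))
    stat <- unname(kw$statistic); p <- kw$p.value
    test <- "kruskal"
  }
  posthoc <- NULL
  if (is.finite(p) && p < alpha) {
    prs <- utils::combn(sessions, 2, simplify = FALSE)
    rows <- lapply(prs, function(pr) {
      a <- tab$value[tab$session_id == pr[1]][order(tab$mouse_id[tab$session_id == pr[1]])]
      b <- tab$value[tab$session_id == pr[2]][order(tab$mouse_id[tab$session_id == pr[2]])]
      paired <- length(a) == length(b)
      w <- if (paired)
        suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
      else suppressWarnings(stats::wilcox.test(a, b))
      data.frame(session_a = pr[1], session_b = pr[2], paired = paired,
                 p_raw = w$p.value,
                 p_adjusted = min(w$p.value * length(prs), 1),
                 stringsAsFactors = FALSE)
    })
    posthoc <- do.call(rbind, rows)
  }
  list(normal = normal, test = test, statistic = stat, p = p,
       posthoc = posthoc)
}
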