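#' Interlimb coordination: phase offsets and temporal overlap
#'
#' The phase offset of a target paw P1 within a reference paw P2's cycle is
#' `phi = (t_s - t_0) / (t_1 - t_0)`, where `[t_0, t_1]` is the period
#' between consecutive reach initiations of the reference paw (the lift-off
#' duration) and `t_s` is the first reach initiation of the target paw
#' falling inside that period. `phi = 0` is in-phase, `phi = 0.5` (180
#' degrees) anti-phase. Offsets are computed in both directions so each paw
#' of a pair serves as reference in turn, and pooled. The Jaccard index
#' complements this cyclic measure with the intersection-over-union of the
#' two paws' total reaching time, which does not assume periodicity.
#'
#' @name coordination
#' @keywords internal
NULL

PAIR_DEFS <- list(
  FF = c("rf", "lf"), HH = c("rh", "lh"),
  DIAG_RFLH = c("rf", "lh"), DIAG_LFRH = c("lf", "rh"),
  LAT_R = c("rf", "rh"), LAT_L = c("lf", "lh"))

#' Directed phase offsets of a target paw within a reference paw's cycles
#'
#' For each consecutive pair `(t0, t1)` of reference reach initiations, if at
#' least one target reach initiation lies in `[t0, t1)`, emit
#' `phi = (ts - t0)/(t1 - t0)` using the first such `ts`. Periods without a
#' target onset emit nothing.
#'
#' @param ref_events,tgt_events [limb_events()] from the same trial.
#' @param time_s,body_speed optional per-frame times and body speed; when
#'   given, each sample carries the mean body speed over its reference
#'   period.
#' @param pair pair label carried into the output.
#' @param meta optional list with `mouse_id`, `session_id`, `trial_id`.
#' @return data.frame of phase samples: `pair`, `reference_paw`,
#'   `target_paw`, `phi`, `phi_deg`, `t0_s`, `t1_s`, `ts_s`,
#'   `liftoff_duration_s`, `body_speed_cm_s`, `location`, metadata columns.
#' @export
directed_phase_offsets <- function(ref_events, tgt_events, time_s = NULL,
                                   body_speed = NULL, pair = NA_character_,
                                   meta = list()) {
  r <- ref_events$reach_onsets_s
  s <- tgt_events$reach_onsets_s
  if (length(r) < 2 || !length(s)) return(empty_phase_table())
  t0 <- r[-length(r)]; t1 <- r[-1]
  ## first target onset inside [t0, t1): index of first s >= t0
  idx <- findInterval(t0, s, left.open = TRUE) + 1L
  ts <- ifelse(idx <= length(s), s[idx], NA_real_)
  keep <- !is.na(ts) & ts >= t0 & ts < t1
  if (!any(keep)) return(empty_phase_table())
  t0 <- t0[keep]; t1 <- t1[keep]; ts <- ts[keep]
  phi <- (ts - t0) / (t1 - t0)
  bs <- rep(NA_real_, length(t0))
  if (!is.null(time_s) && !is.null(body_speed)) {
    v <- body_speed; v[!is.finite(v)] <- 0
    cnt <- as.numeric(is.finite(body_speed))
    cv <- c(0, cumsum(v)); cc <- c(0, cumsum(cnt))
    i0 <- findInterval(t0, time_s) + 1L   # first frame >= t0 (approx)
    i1 <- findInterval(t1, time_s)        # last frame <= t1
    i0 <- pmin(pmax(i0, 1L), length(time_s)); i1 <- pmax(i1, i0)
    npts <- cc[i1 + 1L] - cc[i0]
    bs <- ifelse(npts > 0, (cv[i1 + 1L] - cv[i0]) / npts, NA_real_)
  }
  data.frame(pair = pair, reference_paw = ref_events$paw,
             target_paw = tgt_events$paw,
             phi = phi, phi_deg = 360 * phi,
             t0_s = t0, t1_s = t1, ts_s = ts,
             liftoff_duration_s = t1 - t0,
             body_speed_cm_s = bs, location = "standard",
             mouse_id = meta$mouse_id %||% NA_character_,
             session_id = meta$session_id %||% NA_character_,
             trial_id = meta$trial_id %||% NA_character_,
             stringsAsFactors = FALSE)
}

empty_phase_table <- function() {
  data.frame(pair = character(), reference_paw = character(),
             target_paw = character(), phi = numeric(), phi_deg = numeric(),
             t0_s = numeric(), t1_s = numeric(), ts_s = numeric(),
             liftoff_duration_s = numeric(), body_speed_cm_s = numeric(),
             location = character(), mouse_id = character(),
             session_id = character(), trial_id = character(),
             stringsAsFactors = FALSE)
}

#' Bidirectional phase samples for a paw pair
#'
#' Union of the two directed sample sets, each paw serving as reference in
#' turn; samples are pooled (not averaged pairwise) into the pair's circular
#' distribution, which keeps the pair statistic symmetric.
#'
#' @inheritParams directed_phase_offsets
#' @param events_A,events_B the pair's [limb_events()].
#' @return data.frame of phase samples (see [directed_phase_offsets()]).
#' @export
bidirectional_pair_samples <- function(events_A, events_B, time_s = NULL,
                                       body_speed = NULL,
                                       pair = NA_character_, meta = list()) {
  rbind(
    directed_phase_offsets(events_A, events_B, time_s, body_speed, pair, meta),
    directed_phase_offsets(events_B, events_A, time_s, body_speed, pair, meta))
}

#' All six pair sample sets for one trial
#'
#' Homologous (FF, HH), diagonal (RF-LH, LF-RH) and homolateral (right,
#' left) pairings.
#'
#' @param events named list of per-paw [limb_events()].
#' @param track optional [pose_track()] used to attach body speed.
#' @param body_speed_window_s window for [body_speed()].
#' @return data.frame of phase samples for all pairs.
#' @export
trial_phase_samples <- function(events, track = NULL,
                                body_speed_window_s = 0.5) {
  time_s <- NULL; bs <- NULL; meta <- list()
  if (!is.null(track)) {
    time_s <- track$time_s
    bs <- tryCatch(body_speed(track, body_speed_window_s),
                   error = function(e) NULL)
    if (is.null(bs)) time_s <- NULL
    meta <- track$meta
  }
  out <- lapply(names(PAIR_DEFS), function(p) {
    ab <- PAIR_DEFS[[p]]
    bidirectional_pair_samples(events[[ab[1]]], events[[ab[2]]],
                               time_s, bs, pair = p, meta = meta)
  })
  do.call(rbind, out)
}

#' Drop phase samples with extreme lift-off durations
#'
#' Long reference periods arise when the animal idles between reaches; a
#' target onset early in such a period produces an artificial near-zero
#' (in-phase) offset. Samples whose lift-off duration exceeds the `pct`-th
#' percentile of the whole pooled group are removed; the percentile is
#' computed on the full input before any filtering.
#'
#' @param samples phase-sample table.
#' @param pct percentile in (0, 100]; 100 is the identity.
#' @return filtered table.
#' @export
liftoff_percentile_filter <- function(samples, pct = 90) {
  if (!nrow(samples)) return(samples)
  if (pct >= 100) return(samples)
  cut <- stats::quantile(samples$liftoff_duration_s, pct / 100, names = FALSE,
                         type = 7)
  samples[samples$liftoff_duration_s <= cut, , drop = FALSE]
}

## merge a set of [start, end) intervals; returns matrix with cols start,end
merge_intervals <- function(iv) {
  if (!nrow(iv)) return(iv)
  iv <- iv[order(iv$start_s), , drop = FALSE]
  out_s <- iv$start_s[1]; out_e <- iv$end_s[1]
  ss <- c(); ee <- c()
  for (k in seq_len(nrow(iv))[-1]) {
    if (iv$start_s[k] <= out_e) out_e <- max(out_e, iv$end_s[k])
    else { ss <- c(ss, out_s); ee <- c(ee, out_e)
           out_s <- iv$start_s[k]; out_e <- iv$end_s[k] }
  }
  data.frame(start_s = c(ss, out_s), end_s = c(ee, out_e))
}

interval_total <- function(iv) if (nrow(iv)) sum(iv$end_s - iv$start_s) else 0

intersect_intervals <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(0)
  tot <- 0
  for (k in seq_len(nrow(a))) {
    lo <- pmax(a$start_s[k], b$start_s)
    hi <- pmin(a$end_s[k], b$end_s)
    tot <- tot + sum(pmax(hi - lo, 0))
  }
  tot
}

#' Jaccard temporal-overlap index of two paws' reaching periods
#'
#' `J = |A intersect B| / |A union B|` on the total reaching time of the two
#' paws, by exact interval arithmetic. 0 means strictly sequential reaching,
#' 1 fully synchronous. The degenerate case of an empty union is defined as
#' 0.
#'
#' @param reach_A,reach_B data.frames with `start_s`, `end_s`; intervals
#'   must be disjoint within each paw.
#' @return scalar in `[0, 1]`.
#' @export
jaccard_index <- function(reach_A, reach_B) {
  check_disjoint <- function(iv, who) {
    if (nrow(iv) < 2) return()
    iv <- iv[order(iv$start_s), ]
    if (any(iv$start_s[-1] < iv$end_s[-nrow(iv)]))
      stop("jaccard_index(): overlapping intervals within ", who)
  }
  check_disjoint(reach_A, "reach_A"); check_disjoint(reach_B, "reach_B")
  a <- merge_intervals(reach_A); b <- merge_intervals(reach_B)
  inter <- intersect_intervals(a, b)
  uni <- interval_total(a) + interval_total(b) - inter
  if (uni <= 0) return(0)
  inter / uni
}

#' Trial-level Jaccard overlap for all six pairs
#'
#' @param events named list of per-paw [limb_events()].
#' @param meta optional metadata list.
#' @return data.frame with `pair`, `jaccard`, `mouse_id`, `session_id`,
#'   `trial_id`, `location`.
#' @export
trial_pair_overlaps <- function(events, meta = list()) {
  rows <- lapply(names(PAIR_DEFS), function(p) {
    ab <- PAIR_DEFS[[p]]
    data.frame(pair = p,
               jaccard = jaccard_index(events[[ab[1]]]$reach_intervals,
                                       events[[ab[2]]]$reach_intervals),
               mouse_id = meta$mouse_id %||% NA_character_,
               session_id = meta$session_id %||% NA_character_,
               trial_id = meta$trial_id %||% NA_character_,
               location = "standard", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Circular phase summaries in body-speed bins
#'
#' Samples are assigned to `nbins` half-open speed bins spanning
#' `[lo, hi)` (defaults 0.7 to 8.9 cm/s in four 2.05-cm/s bins); samples
#' outside the span are excluded. Within each bin a circular mean is
#' computed per mouse, then the per-mouse means are summarised at the group
#' level.
#'
#' @param samples phase-sample table with `phi_deg`, `body_speed_cm_s`,
#'   `mouse_id`.
#' @param lo,hi speed span in cm/s.
#' @param nbins number of bins.
#' @return list with `per_mouse` (data.frame: `speed_bin`, `mouse_id`,
#'   `mean_deg`, `r`, `n`) and `group` (data.frame: one [circ_mean()]
#'   summary of the per-mouse means per bin, plus bin edges).
#' @export
phase_by_speed_bins <- function(samples, lo = 0.7, hi = 8.9, nbins = 4) {
  width <- (hi - lo) / nbins
  keep <- is.finite(samples$body_speed_cm_s) &
    samples$body_speed_cm_s >= lo & samples$body_speed_cm_s < hi
  samples <- samples[keep, , drop = FALSE]
  if (!nrow(samples))
    return(list(per_mouse = NULL, group = NULL, bin_width = width))
  samples$speed_bin <- pmin(floor((samples$body_speed_cm_s - lo) / width),
                            nbins - 1)
  pm <- do.call(rbind, lapply(split(samples, list(samples$speed_bin,
                                                  samples$mouse_id),
                                    drop = TRUE), function(sub) {
    s <- circ_mean(sub$phi_deg)
    data.frame(speed_bin = sub$speed_bin[1], mouse_id = sub$mouse_id[1],
               mean_deg = s$mean_direction_deg, r = s$resultant_r,
               n = s$n, stringsAsFactors = FALSE)
  }))
  grp <- do.call(rbind, lapply(split(pm, pm$speed_bin), function(sub) {
    s <- circ_mean(sub$mean_deg)
    data.frame(speed_bin = sub$speed_bin[1],
               bin_lo = lo + sub$speed_bin[1] * width,
               bin_hi = lo + (sub$speed_bin[1] + 1) * width,
               mean_deg = s$mean_direction_deg, r = s$resultant_r,
               rayleigh_p = s$rayleigh_p, n_mice = nrow(sub))
  }))
  list(per_mouse = pm[order(pm$speed_bin, pm$mouse_id), ],
       group = grp[order(grp$speed_bin), ], bin_width = width)
}
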