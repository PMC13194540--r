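#' @importFrom stats approx median sd quantile setNames
#' @importFrom utils read.csv write.csv
NULL

KEYPOINTS <- c("nose", "tail_base", "rf", "lf", "rh", "lh")
PAWS <- c("rf", "lf", "rh", "lh")

#' Camera/wall calibration for ventral-view pose tracks
#'
#' Pixel-to-cm scale, nominal frame rate, and the optional left/right mirror
#' needed because ventral imaging through a transparent wall flips the
#' animal's left and right. The default scale of 44.3 px/cm comes from the
#' tracking-error report of the pose model used to generate this kind of
#' data (3.1 px corresponding to 0.7 mm).
#'
#' @param px_per_cm pixels per centimetre (> 0).
#' @param frame_rate_hz nominal acquisition rate in Hz (> 0; typically 200).
#' @param flip_x mirror x as `x' = wall_width - x` so that "right paw" means
#'   the animal's right.
#' @param origin pixel coordinates `(x0, y0)` mapped to (0, 0) cm.
#' @param wall_width_cm wall width used by the mirror transform.
#' @param wall_height_cm wall height, for reference by downstream analyses.
#' @return an object of class `calibration`.
#' @export
calibration <- function(px_per_cm = 44.3, frame_rate_hz = 200,
                        flip_x = FALSE, origin = c(0, 0),
                        wall_width_cm = 22.5, wall_height_cm = 40) {
  stopifnot(is.finite(px_per_cm), px_per_cm > 0,
            is.finite(frame_rate_hz), frame_rate_hz > 0,
            length(origin) == 2)
  structure(list(px_per_cm = px_per_cm, frame_rate_hz = frame_rate_hz,
                 flip_x = isTRUE(flip_x), origin = as.numeric(origin),
                 wall_width_cm = wall_width_cm,
                 wall_height_cm = wall_height_cm),
            class = "calibration")
}

#' Construct a pose track from calibrated keypoint coordinates
#'
#' A `pose_track` holds one climb: per-frame x/y positions (cm) and tracking
#' confidence for the six keypoints (nose, tail base, and the four paws),
#' with time strictly increasing at the calibrated frame rate. y increases
#' toward the top of the wall.
#'
#' @param time_s strictly increasing times in seconds.
#' @param coords named list; for each keypoint a list with numeric `x`, `y`
#'   (cm) and `conf` in `[0, 1]` (confidence defaults to 1).
#' @param meta list with `mouse_id`, `session_id`, `trial_id`, `wall_type`
#'   (`"standard"` or `"gap"`).
#' @param cal the [calibration()] used.
#' @return an object of class `pose_track`.
#' @export
pose_track <- function(time_s, coords, meta = list(), cal = calibration()) {
  n <- length(time_s)
  stopifnot(n > 1, all(diff(time_s) > 0))
  missing_kp <- setdiff(KEYPOINTS, names(coords))
  if (length(missing_kp))
    stop("pose_track(): missing keypoints: ", paste(missing_kp, collapse = ", "))
  for (kp in KEYPOINTS) {
    c_ <- coords[[kp]]
    if (is.null(c_$conf)) coords[[kp]]$conf <- rep(1, n)
    if (length(c_$x) != n || length(c_$y) != n)
      stop("pose_track(): keypoint '", kp, "' length mismatch")
  }
  meta <- utils::modifyList(
    list(mouse_id = NA_character_, session_id = NA_character_,
         trial_id = NA_character_, wall_type = "standard"), meta)
  structure(list(time_s = as.numeric(time_s), coords = coords[KEYPOINTS],
                 meta = meta, cal = cal),
            class = "pose_track")
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf("pose_track: %d frames @ %g fps, mouse %s session %s trial %s (%s wall)\n",
              length(x$time_s), x$cal$frame_rate_hz, x$meta$mouse_id,
              x$meta$session_id, x$meta$trial_id, x$meta$wall_type))
  invisible(x)
}

#' Extract one keypoint's trajectory
#' @param track a [pose_track()].
#' @param kp keypoint name.
#' @return list with `x`, `y`, `conf` vectors.
#' @export
kp_xy <- function(track, kp) {
  stopifnot(inherits(track, "pose_track"), kp %in% KEYPOINTS)
  track$coords[[kp]]
}

## mouse03_s02_t07_gap.csv -> list(mouse_id = "mouse03", ...)
parse_trial_meta <- function(path) {
  base <- sub("\\.[^.]*$", "", basename(path))
  parts <- strsplit(base, "_")[[1]]
  wall <- if (length(parts) && parts[length(parts)] %in% c("standard", "gap"))
    parts[length(parts)] else "standard"
  grab <- function(prefix) {
    hit <- grep(paste0("^", prefix), parts, value = TRUE)
    if (length(hit)) hit[1] else NA_character_
  }
  list(mouse_id = grab("mouse"), session_id = grab("s"),
       trial_id = grab("t"), wall_type = wall)
}

#' Load one trial's keypoint table
#'
#' Reads a comma-separated keypoint table (one row per frame, columns
#' `<kp>.x`, `<kp>.y`, `<kp>.score` for the six keypoints, optional `frame`
#' column), converts pixels to cm with the calibration, applies the mirror
#' transform when `cal$flip_x`, and parses mouse/session/trial/wall metadata
#' from the file name (`mouse01_s01_t01_standard.csv`) unless supplied.
#'
#' @param path path to the CSV table.
#' @param cal a [calibration()].
#' @param meta optional metadata list overriding the parsed file-name fields.
#' @return a [pose_track()].
#' @export
load_trial <- function(path, cal = calibration(), meta = NULL) {
  tab <- read.csv(path, check.names = FALSE)
  for (kp in KEYPOINTS) {
    for (suf in c("x", "y")) {
      if (!paste(kp, suf, sep = ".") %in% names(tab))
        stop("load_trial(): missing column '", paste(kp, suf, sep = "."),
             "' in ", path)
    }
  }
  n <- nrow(tab)
  if ("frame" %in% names(tab)) {
    fr <- tab$frame
    if (any(abs(diff(fr) - 1) > 1))
      stop("load_trial(): non-uniform frame spacing beyond 1-frame tolerance")
    time_s <- (fr - fr[1]) / cal$frame_rate_hz
  } else {
    time_s <- (seq_len(n) - 1) / cal$frame_rate_hz
  }
  coords <- setNames(vector("list", length(KEYPOINTS)), KEYPOINTS)
  for (kp in KEYPOINTS) {
    x_cm <- (tab[[paste0(kp, ".x")]] - cal$origin[1]) / cal$px_per_cm
    y_cm <- (tab[[paste0(kp, ".y")]] - cal$origin[2]) / cal$px_per_cm
    if (cal$flip_x) x_cm <- cal$wall_width_cm - x_cm
    sc <- tab[[paste0(kp, ".score")]]
    if (is.null(sc)) sc <- rep(1, n)
    coords[[kp]] <- list(x = x_cm, y = y_cm, conf = sc)
  }
  meta <- utils::modifyList(parse_trial_meta(path), as.list(meta %||% list()))
  pose_track(time_s, coords, meta = meta, cal = cal)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pose track back to a keypoint table
#'
#' Inverse of [load_trial()]: cm coordinates are converted back to pixels
#' under the same calibration (including un-mirroring), so that a write/load
#' round trip reproduces coordinates exactly up to floating-point error.
#'
#' @param track a [pose_track()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(track, path) {
  cal <- track$cal
  n <- length(track$time_s)
  out <- data.frame(frame = round(track$time_s * cal$frame_rate_hz))
  for (kp in KEYPOINTS) {
    c_ <- track$coords[[kp]]
    x_cm <- c_$x
    if (cal$flip_x) x_cm <- cal$wall_width_cm - x_cm
    out[[paste0(kp, ".x")]] <- x_cm * cal$px_per_cm + cal$origin[1]
    out[[paste0(kp, ".y")]] <- c_$y * cal$px_per_cm + cal$origin[2]
    out[[paste0(kp, ".score")]] <- c_$conf
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Impute short tracking dropouts and mark analyzable segments
#'
#' Frames where a keypoint is missing (NA) or its confidence falls below
#' `conf_floor` are treated as dropouts. Dropout runs of at most
#' `max_gap_frames` are filled by linear interpolation; longer runs are left
#' missing and split the trial into analyzable segments. The per-keypoint
#' count of imputed frames is attached as attribute `"imputed"` and the
#' frame ranges over which every keypoint is observed as attribute
#' `"segments"`.
#'
#' @param track a [pose_track()].
#' @param max_gap_frames longest interpolable dropout, in frames
#'   (default 10, i.e. 50 ms at 200 fps).
#' @param conf_floor confidence below which a frame counts as missing.
#' @return the imputed [pose_track()].
#' @export
impute_gaps <- function(track, max_gap_frames = 10, conf_floor = 0.5) {
  stopifnot(inherits(track, "pose_track"))
  n <- length(track$time_s)
  imputed <- setNames(integer(length(KEYPOINTS)), KEYPOINTS)
  any_missing <- rep(FALSE, n)
  for (kp in KEYPOINTS) {
    c_ <- track$coords[[kp]]
    bad <- !is.finite(c_$x) | !is.finite(c_$y) | c_$conf < conf_floor
    if (sum(bad) > n / 2)
      stop("impute_gaps(): keypoint '", kp, "' missing in >50% of frames")
    if (!any(bad)) next
    runs <- rle(bad)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    fill <- rep(FALSE, n)
    for (j in seq_along(runs$lengths)) {
      if (!runs$values[j]) next
      interior <- starts[j] > 1L && ends[j] < n
      if (runs$lengths[j] <= max_gap_frames && interior)
        fill[starts[j]:ends[j]] <- TRUE
    }
    if (any(fill)) {
      ok <- !bad
      t <- track$time_s
      c_$x[fill] <- approx(t[ok], c_$x[ok], xout = t[fill])$y
      c_$y[fill] <- approx(t[ok], c_$y[ok], xout = t[fill])$y
      c_$conf[fill] <- conf_floor
      imputed[kp] <- sum(fill)
    }
    still_bad <- bad & !fill
    if (any(still_bad)) {
      c_$x[still_bad] <- NA_real_
      c_$y[still_bad] <- NA_real_
      any_missing <- any_missing | still_bad
    }
    track$coords[[kp]] <- c_
  }
  segs <- if (any(any_missing)) {
    runs <- rle(!any_missing)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    data.frame(start_frame = starts[runs$values], end_frame = ends[runs$values])
  } else {
    data.frame(start_frame = 1L, end_frame = n)
  }
  attr(track, "imputed") <- imputed
  attr(track, "segments") <- segs
  track
}

#' Read a plain-text key-value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment.
#' Values parse to numeric or logical where possible, otherwise stay
#' character.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=:]+)[=:](.*)$", ln))[[1]]
    if (length(m) != 3) next
    key <- trimws(m[2]); val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
      else if (toupper(val) %in% c("TRUE", "FALSE")) as.logical(val)
      else val
  }
  out
}
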