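# Rule-based single-fish trajectory assembly from per-frame detections.
# The linking rules, in order:
#   * start-frame dropping: frames are discarded from the start of the video
#     until exactly one feature is detected (that feature is the fish);
#   * append: a single gated detection extends the trajectory;
#   * hold on empty: no detections -> repeat the last known position;
#   * nearest on multiple: several detections -> the one closest to the last
#     known position wins;
#   * jump gate: a winning detection farther than max_jump_px from the last
#     position is assumed to be a non-fish feature, and the last position is
#     held instead.

#' Tracker configuration
#'
#' @param max_jump_px maximum credible frame-to-frame move of the fish, in
#'   pixels (default 5000); detections beyond it are rejected as non-fish.
#' @param detector a [detector_config()].
#' @return a `tracker_config` list.
#' @export
tracker_config <- function(max_jump_px = 5000, detector = detector_config()) {
  if (!is.finite(max_jump_px) && !identical(max_jump_px, Inf))
    nt_config_error("max_jump_px must be a positive number (Inf allowed)")
  if (max_jump_px <= 0) nt_config_error("max_jump_px must be > 0")
  stopifnot(inherits(detector, "detector_config"))
  structure(list(max_jump_px = max_jump_px, detector = detector),
            class = "tracker_config")
}

new_trajectory <- function(points, fps, start_frame, source_id = "unnamed") {
  structure(list(points = points, fps = fps,
                 start_frame = start_frame, source_id = source_id),
            class = "fish_trajectory")
}

#' @export
print.fish_trajectory <- function(x, ...) {
  cat(sprintf("<fish_trajectory> %d point(s) from frame %d, %.3g fps (%s)\n",
              nrow(x$points), x$start_frame, x$fps, x$source_id))
  if (nrow(x$points)) print(utils::head(x$points, 3))
  invisible(x)
}

#' Find the first trackable frame
#'
#' Frames are dropped from the start of the recording until the difference
#' image yields exactly one detection -- the frame where the only feature is
#' the fish, which anchors the trajectory.
#'
#' @param stack a [frame_stack()].
#' @param base a `base_frame` from [select_base_frame()].
#' @param config a [tracker_config()].
#' @return 0-based index of the first frame with exactly one detection.
#' @export
find_start_frame <- function(stack, base, config = tracker_config()) {
  stopifnot(inherits(stack, "frame_stack"))
  counts <- integer(length(stack$frames))
  for (i in seq_along(stack$frames)) {
    diff <- subtract_background(stack$frames[[i]], base)
    counts[i] <- nrow(detect_features(diff, config$detector))
    if (counts[i] == 1L) return(i - 1L)
  }
  nt_tracking_init_error(
    sprintf("no frame with exactly one detection; per-frame counts: %s",
            paste(counts, collapse = ",")),
    counts = counts)
}

#' Advance the trajectory by one frame
#'
#' Applies the linking rules to one frame's detections given the last tracked
#' point. Empty detections hold the last position (`source = "held"`); a single
#' detection within the jump gate is appended (`"detected"`); multiple
#' detections select the nearest to the last position (`"selected"`, ties
#' resolved by the detector's deterministic ordering); any winner farther than
#' `max_jump_px` is rejected and the last position held.
#'
#' @param last list or one-row data.frame with `x_px`, `y_px`.
#' @param detections data.frame as returned by [detect_features()].
#' @param config a [tracker_config()].
#' @return list with `x_px`, `y_px`, `source`.
#' @export
track_step <- function(last, detections, config = tracker_config()) {
  held <- list(x_px = last$x_px, y_px = last$y_px, source = "held")
  n <- nrow(detections)
  if (n == 0L) return(held)
  if (n == 1L) {
    pick <- 1L
  } else {
    d2 <- (detections$x_px - last$x_px)^2 + (detections$y_px - last$y_px)^2
    pick <- which.min(d2) # ties: first in the detector's sort order
  }
  dist <- sqrt((detections$x_px[pick] - last$x_px)^2 +
               (detections$y_px[pick] - last$y_px)^2)
  if (dist > config$max_jump_px) return(held)
  list(x_px = detections$x_px[pick], y_px = detections$y_px[pick],
       source = if (n == 1L) "detected" else "selected")
}

#' Track a fish through a frame stack
#'
#' Runs the full pipeline on every frame from the start frame (see
#' [find_start_frame()]) to the end of the stack: background subtraction, DoG
#' detection, and rule-based linking. The result has exactly one point per
#' frame; positions are sub-pixel centroids in 0-based pixel coordinates
#' (origin top-left, y downward).
#'
#' @param stack a [frame_stack()].
#' @param base a `base_frame`; defaults to the per-pixel median of the stack.
#' @param config a [tracker_config()].
#' @return a `fish_trajectory`: `points` (data.frame `frame`, `x_px`, `y_px`,
#'   `source`), `fps`, `start_frame`, `source_id`.
#' @export
track <- function(stack, base = select_base_frame(stack), config = tracker_config()) {
  stopifnot(inherits(stack, "frame_stack"))
  start <- find_start_frame(stack, base, config)
  n <- length(stack$frames)
  idx <- (start + 1L):n # 1-based frame positions to process

  x <- numeric(length(idx)); y <- numeric(length(idx))
  src <- character(length(idx))

  first_det <- detect_features(
    subtract_background(stack$frames[[start + 1L]], base), config$detector)
  x[1] <- first_det$x_px[1]; y[1] <- first_det$y_px[1]; src[1] <- "detected"

  last <- list(x_px = x[1], y_px = y[1])
  if (length(idx) > 1L) for (k in 2:length(idx)) {
    det <- detect_features(
      subtract_background(stack$frames[[idx[k]]], base), config$detector)
    p <- track_step(last, det, config)
    x[k] <- p$x_px; y[k] <- p$y_px; src[k] <- p$source
    last <- p
  }
  new_trajectory(
    data.frame(frame = idx - 1L, x_px = x, y_px = y, source = src),
    fps = stack$fps, start_frame = start, source_id = stack$source_id)
}

#' Write a trajectory to CSV
#'
#' Bit-stable format: header `frame,x_px,y_px,source`, positions with six
#' significant digits, preceded by comment lines recording the tool version
#' and configuration hash. Coordinates are 0-based pixels, origin top-left,
#' y downward; frame indices are 0-based.
#'
#' @param traj a `fish_trajectory`.
#' @param path output CSV path.
#' @param cfg optional named list hashed into the header.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, cfg = list()) {
  stopifnot(inherits(traj, "fish_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# noveltank_version: %s", nt_version()),
    sprintf("# config_hash: %s", config_hash(cfg)),
    sprintf("# fps: %.6g", traj$fps),
    sprintf("# start_frame: %d", traj$start_frame),
    sprintf("# source_id: %s", traj$source_id),
    "frame,x_px,y_px,source"), con)
  writeLines(sprintf("%d,%.6g,%.6g,%s", traj$points$frame,
                     traj$points$x_px, traj$points$y_px, traj$points$source), con)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#'
#' @param path CSV path.
#' @param fps frame rate; taken from the file header when present.
#' @return a `fish_trajectory`.
#' @export
read_trajectory_csv <- function(path, fps = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_hdr <- function(key) {
    m <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (length(m)) sub(sprintf("^# %s:\\s*", key), "", m[1]) else NA_character_
  }
  if (is.null(fps)) {
    fps <- suppressWarnings(as.numeric(get_hdr("fps")))
    if (is.na(fps)) nt_input_error("fps not in file header; pass fps explicitly")
  }
  src <- get_hdr("source_id")
  body <- lines[!grepl("^#", lines)]
  pts <- utils::read.csv(text = paste(body, collapse = "\n"),
                         stringsAsFactors = FALSE)
  if (!all(c("frame", "x_px", "y_px", "source") %in% names(pts)))
    nt_format_error("trajectory CSV must have columns frame,x_px,y_px,source")
  new_trajectory(pts, fps = fps, start_frame = pts$frame[1],
                 source_id = if (is.na(src)) basename(path) else src)
}
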