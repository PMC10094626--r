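# Novel tank test readouts on a time-windowed trajectory: distance moved,
# latency to the upper half, freezing duration.

#' Tank geometry and pixel calibration
#'
#' Physical defaults follow the 30 x 20 x 10 cm novel tank filmed from the
#' front, so the image plane spans 30 cm (width) by 20 cm (height). Pixel
#' distances convert to cm through `cm_per_px = width_cm / width_px`; the
#' upper/lower split sits at the geometric midline of the tank ROI.
#'
#' @param width_px,height_px image-plane extent of the tank ROI in pixels.
#' @param width_cm,height_cm,depth_cm physical tank dimensions (defaults
#'   30/20/10 cm).
#' @param midline_row_px row (0-based, y downward) separating upper from lower
#'   half; defaults to `height_px / 2`.
#' @return a `tank_geometry` list with `cm_per_px` filled in.
#' @export
tank_geometry <- function(width_px, height_px, width_cm = 30, height_cm = 20,
                          depth_cm = 10, midline_row_px = height_px / 2) {
  if (width_px <= 0 || height_px <= 0)
    nt_config_error("tank ROI extent must be positive")
  cm_per_px <- width_cm / width_px
  if (!is.finite(cm_per_px) || cm_per_px <= 0)
    nt_config_error("cm_per_px must be > 0")
  if (midline_row_px <= 0 || midline_row_px >= height_px)
    nt_config_error("midline_row_px must lie strictly inside the image")
  structure(list(width_cm = width_cm, height_cm = height_cm, depth_cm = depth_cm,
                 width_px = width_px, height_px = height_px,
                 cm_per_px = cm_per_px, midline_row_px = midline_row_px),
            class = "tank_geometry")
}

#' Analysis window
#'
#' The assay records 7 min per animal and discards the first 2 min, analyzing
#' the remaining 5 min; those protocol values are the defaults.
#'
#' @param skip_s seconds discarded from the start of the recording.
#' @param duration_s length of the analyzed span in seconds.
#' @return an `analysis_window` list.
#' @export
analysis_window <- function(skip_s = 120, duration_s = 300) {
  if (skip_s < 0) nt_config_error("skip_s must be >= 0")
  if (duration_s <= 0) nt_config_error("duration_s must be > 0")
  structure(list(skip_s = skip_s, duration_s = duration_s),
            class = "analysis_window")
}

#' Freezing (immobility) configuration
#'
#' "Total absence of movement" has no literal pixel meaning under tracking
#' jitter, so a frame-to-frame displacement below `speed_threshold_px_per_frame`
#' counts as immobile, and only immobile runs of at least `min_bout_s` count as
#' freezing (the common operational definition in zebrafish behavior work).
#'
#' @param speed_threshold_px_per_frame immobility displacement threshold
#'   (default 0.5 px/frame).
#' @param min_bout_s minimum immobile span counted as freezing (default 1 s).
#' @return a `freezing_config` list.
#' @export
freezing_config <- function(speed_threshold_px_per_frame = 0.5, min_bout_s = 1.0) {
  if (speed_threshold_px_per_frame <= 0) nt_config_error("speed threshold must be > 0")
  if (min_bout_s <= 0) nt_config_error("min_bout_s must be > 0")
  structure(list(speed_threshold_px_per_frame = speed_threshold_px_per_frame,
                 min_bout_s = min_bout_s),
            class = "freezing_config")
}

#' Restrict a trajectory to the analysis window
#'
#' Drops the first `round(skip_s * fps)` points, truncates to at most
#' `round(duration_s * fps)` points, and re-anchors `start_frame`.
#'
#' @param traj a `fish_trajectory`.
#' @param window an [analysis_window()].
#' @return the windowed `fish_trajectory`.
#' @export
apply_analysis_window <- function(traj, window = analysis_window()) {
  stopifnot(inherits(traj, "fish_trajectory"))
  n <- nrow(traj$points)
  drop <- round(window$skip_s * traj$fps)
  if (n <= drop)
    nt_window_error(sprintf(
      "trajectory (%d frames = %.1f s) shorter than the %.1f-s skip",
      n, n / traj$fps, window$skip_s))
  keep_max <- if (is.finite(window$duration_s)) round(window$duration_s * traj$fps) else n
  pts <- traj$points[(drop + 1L):min(n, drop + keep_max), , drop = FALSE]
  rownames(pts) <- NULL
  new_trajectory(pts, fps = traj$fps, start_frame = pts$frame[1],
                 source_id = traj$source_id)
}

step_displacements <- function(traj) {
  p <- traj$points
  if (nrow(p) < 2L) return(numeric(0))
  sqrt(diff(p$x_px)^2 + diff(p$y_px)^2)
}

#' Total distance moved
#'
#' Sum of consecutive Euclidean pixel displacements, converted to cm via the
#' tank calibration. Held points repeat the last position, so they contribute
#' zero by construction.
#'
#' @param traj a (windowed) `fish_trajectory`.
#' @param tank a [tank_geometry()].
#' @return distance in cm.
#' @export
total_distance <- function(traj, tank) {
  stopifnot(inherits(tank, "tank_geometry"))
  sum(step_displacements(traj)) * tank$cm_per_px
}

#' Latency to the upper half
#'
#' Time from the analysis-window start until the tracked centroid first enters
#' the upper half of the tank image (`y_px < midline_row_px`; y increases
#' downward, so smaller y is higher in the tank). A fish already in the upper
#' half scores 0; a fish that never crosses is censored at the window duration.
#'
#' @param traj a windowed `fish_trajectory`.
#' @param tank a [tank_geometry()].
#' @param window the [analysis_window()] used (for the censoring value).
#' @return list with `latency_s` and logical `censored`.
#' @export
latency_to_upper_half <- function(traj, tank, window = analysis_window()) {
  stopifnot(inherits(tank, "tank_geometry"))
  up <- which(traj$points$y_px < tank$midline_row_px)
  if (length(up) == 0L) {
    dur <- if (is.finite(window$duration_s)) window$duration_s
           else nrow(traj$points) / traj$fps
    return(list(latency_s = dur, censored = TRUE))
  }
  list(latency_s = (up[1] - 1L) / traj$fps, censored = FALSE)
}

#' Freezing duration
#'
#' Each inter-frame step is immobile iff its displacement falls below the
#' speed threshold; maximal immobile runs of at least `round(min_bout_s * fps)`
#' steps are freezing bouts, and the total bout time (run length / fps) is
#' returned. A fully stationary window therefore scores its step count / fps,
#' one inter-frame quantum less than the window duration.
#'
#' @param traj a windowed `fish_trajectory`.
#' @param config a [freezing_config()].
#' @return freezing time in seconds.
#' @export
freezing_duration <- function(traj, config = freezing_config()) {
  stopifnot(inherits(config, "freezing_config"))
  d <- step_displacements(traj)
  if (length(d) == 0L) return(0)
  immobile <- d < config$speed_threshold_px_per_frame
  r <- rle(immobile)
  min_len <- round(config$min_bout_s * traj$fps)
  bouts <- r$lengths[r$values & r$lengths >= min_len]
  sum(bouts) / traj$fps
}

#' Summarize novel tank behavior
#'
#' Applies the analysis window and computes the three readouts in one record.
#'
#' @param traj a `fish_trajectory` (unwindowed).
#' @param tank a [tank_geometry()].
#' @param window an [analysis_window()].
#' @param freezing a [freezing_config()].
#' @return a `behavior_metrics` list: `distance_cm`, `latency_s`,
#'   `latency_censored`, `freezing_s`, `window`, `n_frames_analyzed`,
#'   `source_id`.
#' @export
summarize_behavior <- function(traj, tank, window = analysis_window(),
                               freezing = freezing_config()) {
  w <- apply_analysis_window(traj, window)
  lat <- latency_to_upper_half(w, tank, window)
  structure(list(
    distance_cm = total_distance(w, tank),
    latency_s = lat$latency_s,
    latency_censored = lat$censored,
    freezing_s = freezing_duration(w, freezing),
    window = window,
    n_frames_analyzed = nrow(w$points),
    source_id = traj$source_id), class = "behavior_metrics")
}

#' @export
print.behavior_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "<behavior_metrics> %s\n  distance: %.2f cm\n  latency to upper half: %.2f s%s\n",
    "  freezing: %.2f s\n  frames analyzed: %d\n"),
    x$source_id, x$distance_cm, x$latency_s,
    if (x$latency_censored) " (censored)" else "", x$freezing_s,
    x$n_frames_analyzed))
  invisible(x)
}

#' Write behavior metrics to CSV
#'
#' One row per video, with the tool version and configuration hash embedded as
#' comment lines.
#'
#' @param metrics a `behavior_metrics` or list of them.
#' @param path output CSV path.
#' @param cfg optional named list hashed into the header.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path, cfg = list()) {
  if (inherits(metrics, "behavior_metrics")) metrics <- list(metrics)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# noveltank_version: %s", nt_version()),
    sprintf("# config_hash: %s", config_hash(cfg)),
    "source_id,distance_cm,latency_s,latency_censored,freezing_s,n_frames_analyzed"),
    con)
  for (m in metrics)
    writeLines(sprintf("%s,%.6g,%.6g,%s,%.6g,%d", m$source_id, m$distance_cm,
                       m$latency_s, tolower(m$latency_censored), m$freezing_s,
                       m$n_frames_analyzed), con)
  invisible(path)
}
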