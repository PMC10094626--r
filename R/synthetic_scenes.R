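# Ground-truth behavior scripts and synthetic tank-scene rendering. The
# generator emulates what the tracker must survive in a real recording: a
# single bright fish blob over a static background, an optional near-bottom
# mirror reflection, static distractor features appearing mid-video, detection
# dropout frames, and additive Gaussian sensor noise.

#' Behavior script: a parametric ground-truth trajectory
#'
#' Four stereotyped behaviors: `"straight-line"` (constant heading),
#' `"random-walk"` (seeded heading diffusion), `"bottom-dweller"` (random walk
#' confined below the midline; never crosses), and `"scripted-crossing"`
#' (confined below the midline until `crossing_time_s`, then swims up).
#' A freeze schedule pins the position during the given intervals.
#'
#' @param kind one of the four behaviors above.
#' @param speed_px_per_frame swim speed in px/frame.
#' @param freeze_schedule list of `c(start_s, end_s)` immobility intervals;
#'   must not overlap.
#' @param crossing_time_s target first-crossing time for `"scripted-crossing"`.
#' @param seed integer RNG seed; identical seed and parameters give an
#'   identical path.
#' @param fps frames per second.
#' @param duration_s script length in seconds.
#' @param bounds named list `xmin, xmax, ymin, ymax`: reflecting walls of the
#'   walkable area, in 0-based pixel coordinates (y downward).
#' @param midline_row_px upper/lower-half boundary used by the confined kinds.
#' @param turn_sd_rad heading diffusion of the random walk (rad/frame).
#' @param start_xy optional `c(x, y)` start position; by default the start is
#'   drawn uniformly inside the walkable area (the confined kinds start below
#'   the midline).
#' @return a `behavior_script` list.
#' @export
behavior_script <- function(kind = c("random-walk", "straight-line",
                                     "bottom-dweller", "scripted-crossing"),
                            speed_px_per_frame = 3,
                            freeze_schedule = list(),
                            crossing_time_s = NULL,
                            seed = 1L, fps = 10, duration_s = 60,
                            bounds = list(xmin = 10, xmax = 309, ymin = 10, ymax = 190),
                            midline_row_px = NULL,
                            turn_sd_rad = 0.5, start_xy = NULL) {
  kind <- match.arg(kind)
  if (speed_px_per_frame <= 0) nt_config_error("speed must be > 0")
  if (fps <= 0 || duration_s <= 0) nt_config_error("fps and duration must be > 0")
  if (bounds$xmax <= bounds$xmin || bounds$ymax <= bounds$ymin)
    nt_config_error("bounds must span a positive area")
  if (length(freeze_schedule)) {
    iv <- do.call(rbind, freeze_schedule)
    if (any(iv[, 2] <= iv[, 1])) nt_config_error("freeze intervals must have end > start")
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (nrow(iv) > 1 && any(iv[-1, 1] < iv[-nrow(iv), 2]))
      nt_config_error("freeze intervals overlap")
  }
  if (kind == "scripted-crossing" && is.null(crossing_time_s))
    nt_config_error("scripted-crossing needs crossing_time_s")
  if (is.null(midline_row_px)) midline_row_px <- (bounds$ymin + bounds$ymax) / 2
  if (!is.null(start_xy) &&
      (start_xy[1] < bounds$xmin || start_xy[1] > bounds$xmax ||
       start_xy[2] < bounds$ymin || start_xy[2] > bounds$ymax))
    nt_config_error("start_xy must lie inside the bounds")
  structure(list(kind = kind, speed_px_per_frame = speed_px_per_frame,
                 freeze_schedule = freeze_schedule,
                 crossing_time_s = crossing_time_s, seed = as.integer(seed),
                 fps = fps, duration_s = duration_s, bounds = bounds,
                 midline_row_px = midline_row_px, turn_sd_rad = turn_sd_rad,
                 start_xy = start_xy),
            class = "behavior_script")
}

# reflect a scalar into [lo, hi] (fold at the walls)
reflect_into <- function(v, lo, hi) {
  span <- hi - lo
  while (v < lo || v > hi) {
    if (v < lo) v <- 2 * lo - v
    if (v > hi) v <- 2 * hi - v
  }
  v
}

#' Generate the ground-truth path of a behavior script
#'
#' @param script a [behavior_script()].
#' @return a `behavior_truth` object: data.frame `frame` (0-based), `x_px`,
#'   `y_px`, `immobile` (a frame is immobile when it did not move from the
#'   previous frame), with attributes `fps`, `midline_row_px`,
#'   `first_crossing_frame` (0-based, `NA` if the path never enters the upper
#'   half) and `script`.
#' @export
make_trajectory <- function(script) {
  stopifnot(inherits(script, "behavior_script"))
  n <- round(script$duration_s * script$fps)
  b <- script$bounds
  mid <- script$midline_row_px
  frozen <- logical(n)
  for (iv in script$freeze_schedule) {
    f0 <- floor(iv[1] * script$fps); f1 <- ceiling(iv[2] * script$fps) - 1L
    frozen[seq.int(max(1L, f0 + 1L), min(n, f1 + 1L))] <- TRUE
  }

  x <- numeric(n); y <- numeric(n)
  with_seed(script$seed, {
    lower_band <- c(max(b$ymin, mid + 8), b$ymax) # confinement below the midline
    start_y <- switch(script$kind,
      "bottom-dweller" = , "scripted-crossing" =
        stats::runif(1, lower_band[1], lower_band[2]),
      stats::runif(1, b$ymin, b$ymax))
    x[1] <- stats::runif(1, b$xmin, b$xmax)
    y[1] <- start_y
    if (!is.null(script$start_xy)) {
      x[1] <- script$start_xy[1]
      y[1] <- script$start_xy[2]
    }
    theta <- stats::runif(1, 0, 2 * pi)

    cross_frame <- if (script$kind == "scripted-crossing")
      round(script$crossing_time_s * script$fps) else NA_integer_

    for (i in seq_len(n - 1L)) {
      if (frozen[i + 1L]) { x[i + 1L] <- x[i]; y[i + 1L] <- y[i]; next }
      ylim <- switch(script$kind,
        "bottom-dweller" = lower_band,
        "scripted-crossing" = if (i < cross_frame) lower_band else c(b$ymin, b$ymax),
        c(b$ymin, b$ymax))
      if (script$kind == "straight-line") {
        dx <- cos(theta) * script$speed_px_per_frame
        dy <- sin(theta) * script$speed_px_per_frame
      } else if (script$kind == "scripted-crossing" &&
                 i >= cross_frame && y[i] >= mid) {
        # head straight up until the midline is crossed
        dx <- 0; dy <- -script$speed_px_per_frame
      } else {
        theta <- theta + stats::rnorm(1, 0, script$turn_sd_rad)
        dx <- cos(theta) * script$speed_px_per_frame
        dy <- sin(theta) * script$speed_px_per_frame
      }
      x[i + 1L] <- reflect_into(x[i] + dx, b$xmin, b$xmax)
      y[i + 1L] <- reflect_into(y[i] + dy, ylim[1], ylim[2])
    }
  })

  immobile <- c(FALSE, sqrt(diff(x)^2 + diff(y)^2) < 1e-9)
  crossing <- which(y < mid)
  truth <- data.frame(frame = 0:(n - 1L), x_px = x, y_px = y, immobile = immobile)
  structure(truth, class = c("behavior_truth", "data.frame"),
            fps = script$fps, midline_row_px = mid,
            first_crossing_frame = if (length(crossing)) crossing[1] - 1L else NA_integer_,
            script = script)
}

#' Scene rendering configuration
#'
#' @param width_px,height_px raster size.
#' @param background constant background intensity (0-255) or a full raster.
#' @param blob_sigma_px Gaussian radius of the fish blob.
#' @param blob_peak_intensity peak intensity added by the fish blob; must
#'   exceed `noise_sd`.
#' @param reflection list `enabled`, `gain` (< 1), `floor_row` (mirror row,
#'   0-based) and `active_below_row` (reflection rendered only when the fish is
#'   below this row).
#' @param dropout_frames 0-based frame indices rendered without the fish (and
#'   its reflection), emulating detection dropout.
#' @param distractors data.frame `x, y, sigma, intensity, from_frame`: static
#'   blobs rendered from `from_frame` (0-based) onward.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param noise_seed RNG seed for the noise; rendering is deterministic given
#'   the seed.
#' @return a `scene_config` list.
#' @export
scene_config <- function(width_px = 320, height_px = 240, background = 30,
                         blob_sigma_px = 3, blob_peak_intensity = 180,
                         reflection = list(enabled = FALSE, gain = 0.4,
                                           floor_row = height_px - 36,
                                           active_below_row = height_px - 66),
                         dropout_frames = integer(0),
                         distractors = NULL,
                         noise_sd = 0, noise_seed = 1L) {
  if (noise_sd < 0 || blob_peak_intensity <= noise_sd)
    nt_config_error("blob_peak_intensity must exceed noise_sd >= 0")
  if (!is.null(distractors) &&
      !all(c("x", "y", "sigma", "intensity") %in% names(distractors)))
    nt_config_error("distractors need columns x, y, sigma, intensity")
  if (!is.null(distractors) && is.null(distractors$from_frame))
    distractors$from_frame <- 0L
  structure(list(width_px = width_px, height_px = height_px,
                 background = background, blob_sigma_px = blob_sigma_px,
                 blob_peak_intensity = blob_peak_intensity,
                 reflection = reflection, dropout_frames = dropout_frames,
                 distractors = distractors, noise_sd = noise_sd,
                 noise_seed = as.integer(noise_seed)),
            class = "scene_config")
}

# additive isotropic Gaussian blob, separable outer-product evaluation
add_blob <- function(frame, x, y, sigma, peak) {
  gy <- exp(-((seq_len(nrow(frame)) - 1 - y)^2) / (2 * sigma^2))
  gx <- exp(-((seq_len(ncol(frame)) - 1 - x)^2) / (2 * sigma^2))
  frame + peak * (gy %o% gx)
}

#' Render a ground-truth path into a synthetic video
#'
#' Each frame is background + fish blob (+ mirrored reflection blob when the
#' fish is below the activation row) + distractors + seeded Gaussian noise,
#' clipped to the 0-255 intensity domain. Dropout frames omit the fish and its
#' reflection.
#'
#' @param truth a `behavior_truth` from [make_trajectory()].
#' @param scene a [scene_config()].
#' @param source_id identifier stored in the frame stack.
#' @return a [frame_stack()].
#' @export
render_video <- function(truth, scene = scene_config(), source_id = "synthetic") {
  stopifnot(inherits(truth, "behavior_truth"), inherits(scene, "scene_config"))
  H <- scene$height_px; W <- scene$width_px
  if (any(truth$x_px < 0 | truth$x_px > W - 1 | truth$y_px < 0 | truth$y_px > H - 1))
    nt_config_error("path leaves the raster; enlarge the scene or shrink the bounds")
  bg <- if (is.matrix(scene$background)) scene$background
        else matrix(scene$background, H, W)
  refl <- scene$reflection
  n <- nrow(truth)
  frames <- vector("list", n)
  with_seed(scene$noise_seed, {
    for (i in seq_len(n)) {
      f <- bg
      if (!is.null(scene$distractors)) {
        d <- scene$distractors
        for (k in seq_len(nrow(d))) if (truth$frame[i] >= d$from_frame[k])
          f <- add_blob(f, d$x[k], d$y[k], d$sigma[k], d$intensity[k])
      }
      if (!(truth$frame[i] %in% scene$dropout_frames)) {
        f <- add_blob(f, truth$x_px[i], truth$y_px[i], scene$blob_sigma_px,
                      scene$blob_peak_intensity)
        if (isTRUE(refl$enabled) && truth$y_px[i] > refl$active_below_row) {
          ry <- 2 * refl$floor_row - truth$y_px[i]
          if (ry <= H - 1)
            f <- add_blob(f, truth$x_px[i], ry, scene$blob_sigma_px,
                          refl$gain * scene$blob_peak_intensity)
        }
      }
      if (scene$noise_sd > 0)
        f <- f + matrix(stats::rnorm(H * W, 0, scene$noise_sd), H, W)
      frames[[i]] <- pmin(pmax(f, 0), 255)
    }
  })
  frame_stack(frames, fps = attr(truth, "fps"), source_id = source_id)
}

#' Write a ground-truth path to CSV
#'
#' Columns `frame, x_px, y_px, immobile`; bit-stable formatting with version
#' and configuration-hash header lines.
#'
#' @param truth a `behavior_truth`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  stopifnot(inherits(truth, "behavior_truth"))
  s <- attr(truth, "script")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# noveltank_version: %s", nt_version()),
    sprintf("# config_hash: %s", config_hash(list(
      kind = s$kind, seed = s$seed, fps = s$fps, duration_s = s$duration_s,
      speed = s$speed_px_per_frame))),
    sprintf("# fps: %.6g", attr(truth, "fps")),
    "frame,x_px,y_px,immobile"), con)
  writeLines(sprintf("%d,%.6g,%.6g,%d", truth$frame, truth$x_px, truth$y_px,
                     as.integer(truth$immobile)), con)
  invisible(path)
}

#' Convert a ground-truth path into a trajectory
#'
#' Useful for metric-recovery checks that bypass rendering and tracking: the
#' scripted path itself becomes a `fish_trajectory`.
#'
#' @param truth a `behavior_truth`.
#' @param source_id identifier for the resulting trajectory.
#' @return a `fish_trajectory`.
#' @export
truth_as_trajectory <- function(truth, source_id = "truth") {
  new_trajectory(
    data.frame(frame = truth$frame, x_px = truth$x_px, y_px = truth$y_px,
               source = "detected"),
    fps = attr(truth, "fps"), start_frame = truth$frame[1], source_id = source_id)
}
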