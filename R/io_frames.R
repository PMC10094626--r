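# Frame-stack IO: loading recordings into a uniform grayscale representation,
# base-frame selection and background subtraction. Intensities are kept on a
# 0-255 float scale regardless of source bit depth so detector thresholds have
# a single meaning.

#' Construct a frame stack
#'
#' A frame stack is the tracker's input: an ordered sequence of grayscale
#' frames sharing one geometry, plus the frame rate needed to convert frame
#' counts into seconds. Intensities are floats on a 0-255 scale.
#'
#' @param frames list of numeric matrices (rows = image y, columns = image x),
#'   all of identical dimension, values finite and >= 0.
#' @param fps frames per second (> 0).
#' @param source_id free-text identifier carried into downstream outputs.
#' @return an object of class `frame_stack` with fields `frames`, `fps`,
#'   `height_px`, `width_px`, `source_id`.
#' @export
#' @examples
#' fs <- frame_stack(list(matrix(0, 4, 4), matrix(1, 4, 4)), fps = 10)
#' fs$width_px
frame_stack <- function(frames, fps, source_id = "unnamed") {
  if (!is.list(frames) || length(frames) < 1L)
    nt_input_error("a frame stack needs at least one frame")
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    nt_input_error("fps must be a single positive number")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    nt_format_error("all frames must share identical dimensions")
  for (f in frames) {
    if (!is.matrix(f) || !is.numeric(f))
      nt_format_error("each frame must be a numeric matrix")
    if (any(!is.finite(f)) || any(f < 0))
      nt_format_error("frame intensities must be finite and >= 0")
  }
  structure(
    list(frames = frames, fps = as.numeric(fps),
         height_px = dims[1, 1], width_px = dims[2, 1],
         source_id = as.character(source_id)),
    class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("<frame_stack> %d frame(s), %dx%d px, %.3g fps, source=%s\n",
              length(x$frames), x$width_px, x$height_px, x$fps, x$source_id))
  invisible(x)
}

#' Convert a color raster to grayscale
#'
#' Fixed luma weights 0.299 (R), 0.587 (G), 0.114 (B); the standard video luma
#' combination, chosen for determinism across sources.
#'
#' @param frame H x W x 3 numeric array.
#' @return H x W numeric matrix.
#' @export
#' @examples
#' to_grayscale(array(255, c(2, 2, 3)))[1, 1] # 255
to_grayscale <- function(frame) {
  if (length(dim(frame)) != 3L || dim(frame)[3] != 3L)
    nt_format_error("expected an H x W x 3 color raster")
  if (any(!is.finite(frame)))
    nt_format_error("color raster contains non-finite values")
  0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
}

# Read one image file as a 0-255 grayscale matrix.
read_image_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    "tif" = , "tiff" = tiff::readTIFF(path),
    "png" = png::readPNG(path),
    nt_format_error(sprintf("unsupported image format: '%s'", ext)))
  image_to_gray255(img)
}

# Normalize a decoded raster (0-1 or 0-255, gray or RGB(A)) to 0-255 grayscale.
image_to_gray255 <- function(img) {
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3L) {
      img <- img[, , 1:3, drop = FALSE]
      scale <- if (max(img) <= 1) 255 else 1
      return(to_grayscale(img * scale))
    }
    img <- img[, , 1]
  }
  if (max(img) <= 1) img <- img * 255
  as.matrix(img)
}

#' Load a recording into a frame stack
#'
#' Supported sources: a multi-page TIFF file, or a directory of
#' lexicographically ordered PNG/TIFF images (one frame per file). Color
#' frames are converted to grayscale on load. TIFF and PNG carry no frame-rate
#' metadata, so `fps` must be supplied.
#'
#' @param source path to a multi-page TIFF, or a directory of images.
#' @param fps frames per second of the recording.
#' @param source_id identifier; defaults to the file/directory name.
#' @return a [frame_stack()].
#' @export
load_frames <- function(source, fps, source_id = basename(source)) {
  if (missing(fps) || is.null(fps))
    nt_input_error("fps must be supplied: TIFF/PNG sources carry no frame-rate metadata")
  if (length(source) != 1L || !file.exists(source))
    nt_input_error(sprintf("unreadable source: '%s'", source))
  if (dir.exists(source)) {
    files <- sort(list.files(source, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L)
      nt_input_error(sprintf("no image files found in directory '%s'", source))
    frames <- lapply(files, read_image_gray)
  } else {
    ext <- tolower(tools::file_ext(source))
    if (!ext %in% c("tif", "tiff"))
      nt_format_error(sprintf("unsupported source format: '%s' (use multi-page TIFF or an image directory)", ext))
    pages <- tiff::readTIFF(source, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) == 0L) nt_input_error("source contains zero frames")
    frames <- lapply(pages, image_to_gray255)
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    nt_format_error("frames in source have inconsistent shapes")
  frame_stack(frames, fps = fps, source_id = source_id)
}

#' Write a frame stack to a multi-page TIFF
#'
#' Frames are stored as 8-bit grayscale (values clipped to 0-255 and rounded),
#' matching the intensity domain the pipeline operates on.
#'
#' @param stack a [frame_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_frames_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  pages <- lapply(stack$frames, function(f) pmin(pmax(round(f), 0), 255) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Select the base (background) frame of a stack
#'
#' The base frame is the static scene subtracted from every frame so only the
#' moving animal remains. Two modes: `"index"` returns a chosen frame verbatim;
#' `"median"` (default) computes the per-pixel median over an evenly strided
#' subsample of at most 101 frames, which equals the true static background
#' whenever the animal occupies each pixel in fewer than half of the sampled
#' frames.
#'
#' @param stack a [frame_stack()].
#' @param mode `"median"` or `"index"`.
#' @param index 0-based frame index (required for `mode = "index"`).
#' @return an object of class `base_frame` with fields `raster`, `mode`,
#'   `origin_index`.
#' @export
select_base_frame <- function(stack, mode = c("median", "index"), index = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  mode <- match.arg(mode)
  n <- length(stack$frames)
  if (mode == "index") {
    if (is.null(index) || length(index) != 1L || is.na(index))
      nt_input_error("mode='index' requires an index")
    if (index < 0 || index >= n)
      nt_input_error(sprintf("base-frame index %d out of range [0, %d]", index, n - 1L))
    raster <- stack$frames[[index + 1L]]
  } else {
    if (n < 3L)
      nt_input_error("per-pixel-median base frame needs at least 3 frames")
    stride <- ceiling(n / 101)
    sel <- seq(1L, n, by = stride)
    flat <- vapply(stack$frames[sel], as.vector,
                   numeric(stack$height_px * stack$width_px))
    raster <- matrix(cpp_row_medians(flat), stack$height_px, stack$width_px)
    index <- NULL
  }
  structure(list(raster = raster, mode = mode, origin_index = index),
            class = "base_frame")
}

#' Background subtraction
#'
#' Element-wise absolute difference between a frame and the base frame, so the
#' fish is bright whether it is darker or lighter than the background.
#'
#' @param frame numeric matrix.
#' @param base a `base_frame` or a numeric matrix.
#' @return numeric matrix of the same shape, all values >= 0.
#' @export
subtract_background <- function(frame, base) {
  raster <- if (inherits(base, "base_frame")) base$raster else base
  if (!identical(dim(frame), dim(raster)))
    nt_format_error(sprintf(
      "frame (%dx%d) and base (%dx%d) shapes differ",
      nrow(frame), ncol(frame), nrow(raster), ncol(raster)))
  abs(frame - raster)
}
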