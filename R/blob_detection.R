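# Difference-of-Gaussians blob detection on background-subtracted frames.
# The detector is deliberately single-scale: one fish, one characteristic size.

#' Detector configuration
#'
#' Defaults assume a fish subtending roughly 5-15 px, as in a typical
#' 30-cm-tank recording at a few hundred pixels of width: a centre scale of
#' 3 px, the classic 1.6 scale ratio, a response threshold of 5 on the 0-255
#' intensity scale, and an 8-px merge radius for nearby maxima.
#'
#' @param sigma_small centre Gaussian scale in px (> 0).
#' @param sigma_large surround Gaussian scale in px (> sigma_small); defaults
#'   to `1.6 * sigma_small`.
#' @param response_threshold minimum DoG peak magnitude (intensity units, > 0).
#' @param min_separation_px maxima closer than this are merged to the strongest.
#' @return a `detector_config` list.
#' @export
detector_config <- function(sigma_small = 3, sigma_large = 1.6 * sigma_small,
                            response_threshold = 5, min_separation_px = 8) {
  if (!is.finite(sigma_small) || sigma_small <= 0)
    nt_config_error("sigma_small must be > 0")
  if (!is.finite(sigma_large) || sigma_large <= sigma_small)
    nt_config_error("sigma_large must exceed sigma_small")
  if (!is.finite(response_threshold) || response_threshold <= 0)
    nt_config_error("response_threshold must be > 0")
  if (!is.finite(min_separation_px) || min_separation_px < 0)
    nt_config_error("min_separation_px must be >= 0")
  structure(list(sigma_small = sigma_small, sigma_large = sigma_large,
                 response_threshold = response_threshold,
                 min_separation_px = min_separation_px),
            class = "detector_config")
}

# Truncated, normalized 1-D Gaussian kernel; radius 3.5 sigma keeps the
# discarded tail below 5e-4 of the mass.
gaussian_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3.5 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian blur with reflective boundary
#'
#' Separable convolution with a truncated (3.5 sigma), normalized Gaussian;
#' boundaries are handled by half-sample mirror reflection, which avoids the
#' spurious edge responses a zero-padded blur would create.
#'
#' @param image numeric matrix.
#' @param sigma Gaussian scale in px.
#' @return blurred matrix, same shape.
#' @export
gaussian_blur <- function(image, sigma) {
  cpp_sep_convolve_reflect(image, gaussian_kernel(sigma))
}

#' Difference-of-Gaussians response
#'
#' Band-pass response `blur(image, sigma_small) - blur(image, sigma_large)`:
#' positive peaks mark bright blobs of size between the two scales.
#'
#' @param image background-subtracted frame (numeric matrix).
#' @param sigma_small,sigma_large Gaussian scales, `sigma_large > sigma_small`.
#' @return response matrix, same shape as `image`.
#' @export
dog_response <- function(image, sigma_small = 3, sigma_large = 1.6 * sigma_small) {
  if (sigma_large <= sigma_small)
    nt_config_error("sigma_large must exceed sigma_small")
  gaussian_blur(image, sigma_small) - gaussian_blur(image, sigma_large)
}

#' Detect blob features in a difference image
#'
#' Local maxima (8-neighborhood) of the DoG response above
#' `response_threshold`; maxima closer than `min_separation_px` are merged to
#' the strongest. Each detection's centroid is the response-weighted centroid
#' of the connected thresholded support region containing its maximum, giving
#' sub-pixel localization. Coordinates are 0-based, origin at the top-left,
#' `y_px` increasing downward.
#'
#' @param image background-subtracted frame (numeric matrix).
#' @param config a [detector_config()].
#' @return data.frame with columns `x_px`, `y_px`, `response`, `area_px`,
#'   sorted by descending response (ties: row-major position). Zero rows when
#'   nothing exceeds the threshold.
#' @export
detect_features <- function(image, config = detector_config()) {
  stopifnot(inherits(config, "detector_config"))
  resp <- dog_response(image, config$sigma_small, config$sigma_large)
  thr <- config$response_threshold
  nr <- nrow(resp); nc <- ncol(resp)

  above <- resp > thr
  if (!any(above)) return(empty_detections())

  # local maxima: >= all 8 neighbors (plateaus yield adjacent candidates that
  # the merge step collapses), and strictly above the threshold
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- resp
  ismax <- above
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    ismax <- ismax & (resp >= pad[(2:(nr + 1L)) + di, (2:(nc + 1L)) + dj])
  }
  idx <- which(ismax)
  if (length(idx) == 0L) return(empty_detections())

  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  val <- resp[idx]
  # deterministic order: descending response, ties by row-major (y, then x)
  ord <- order(-val, row, col)
  row <- row[ord]; col <- col[ord]; val <- val[ord]

  # non-maximum suppression: merge maxima within min_separation_px (keep strongest)
  keep <- logical(length(val))
  for (i in seq_along(val)) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- (row[i] - row[keep])^2 + (col[i] - col[keep])^2
    if (all(d2 >= config$min_separation_px^2)) keep[i] <- TRUE
  }
  row <- row[keep]; col <- col[keep]; val <- val[keep]

  # support regions: connected components of the thresholded response
  labels <- EBImage::bwlabel(above)
  lab <- labels[cbind(row, col)]
  # one detection per component: the strongest maximum claims it
  first <- !duplicated(lab)
  row <- row[first]; col <- col[first]; val <- val[first]; lab <- lab[first]

  out <- lapply(seq_along(lab), function(i) {
    px <- which(labels == lab[i])
    pr <- ((px - 1L) %% nr) + 1L
    pc <- ((px - 1L) %/% nr) + 1L
    w <- resp[px]
    data.frame(x_px = sum(w * (pc - 1L)) / sum(w),
               y_px = sum(w * (pr - 1L)) / sum(w),
               response = val[i], area_px = length(px))
  })
  out <- do.call(rbind, out)
  # re-sort: merging can keep a weaker component-representative
  ord <- order(-out$response, out$y_px, out$x_px)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_detections <- function() {
  data.frame(x_px = numeric(0), y_px = numeric(0),
             response = numeric(0), area_px = integer(0))
}
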