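#' Trinary lineage label map
#'
#' Container for a per-pixel classification of a whole mount into
#' `NON_TISSUE` (0), `RED` (1, tdTomato) and `GREEN` (2, EGFP), with the
#' physical pixel size attached.
#'
#' @param labels Integer matrix with values in `{0, 1, 2}`.
#' @param pixel_size Micrometres per pixel (> 0).
#' @return A list of class `label_map`.
#' @export
label_map <- function(labels, pixel_size) {
  check_positive(pixel_size, "pixel_size")
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (!all(labels %in% c(LBL_NON_TISSUE, LBL_RED, LBL_GREEN))) {
    stop_param("`labels` must only contain 0 (non-tissue), 1 (red), 2 (green).")
  }
  structure(list(labels = labels, pixel_size = pixel_size),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf(
    "<label_map> %d x %d px, %.3g um/px | red %.1f%%, green %.1f%%, non-tissue %.1f%%\n",
    nrow(x$labels), ncol(x$labels), x$pixel_size,
    100 * mean(x$labels == LBL_RED), 100 * mean(x$labels == LBL_GREEN),
    100 * mean(x$labels == LBL_NON_TISSUE)))
  invisible(x)
}

#' Rolling-ball background subtraction
#'
#' Estimates a smooth background as the grayscale morphological opening of
#' the channel with a disc structuring element of the given radius and
#' subtracts it, clipping at zero. Features narrower than the disc survive
#' subtraction; smooth large-scale background (uneven illumination,
#' autofluorescence) is removed.
#'
#' @param channel Numeric intensity matrix (values >= 0).
#' @param rolling_radius Disc radius in pixels (>= 1, smaller than the
#'   image in at least one dimension).
#' @return Background-subtracted matrix, same shape.
#' @export
subtract_background <- function(channel, rolling_radius = 40) {
  if (rolling_radius < 1) {
    stop_param("`rolling_radius` must be >= 1.", field = "rolling_radius")
  }
  if (rolling_radius > nrow(channel) && rolling_radius > ncol(channel)) {
    stop_param("`rolling_radius` exceeds both image dimensions.",
               field = "rolling_radius")
  }
  brush <- EBImage::makeBrush(2 * as.integer(rolling_radius) + 1L, "disc")
  bg <- EBImage::imageData(EBImage::opening(EBImage::Image(channel), brush))
  pmax(channel - bg, 0)
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Tile-wise histogram equalization with a clip limit, preserving the
#' input intensity range. Thin wrapper mapping a tile size in pixels and a
#' clip fraction onto EBImage's tile-count/limit parameterisation.
#'
#' @param channel Numeric intensity matrix.
#' @param tile_size Approximate tile edge in pixels (>= 8).
#' @param clip_limit Histogram clip limit as a fraction of the tile's
#'   pixel count per bin (256 bins).
#' @return Equalized matrix, same shape and intensity range as the input.
#' @export
enhance_local_contrast <- function(channel, tile_size = 64,
                                   clip_limit = 0.01) {
  if (tile_size < 8) stop_param("`tile_size` must be >= 8.",
                                field = "tile_size")
  check_positive(clip_limit, "clip_limit")
  rng <- range(channel)
  if (diff(rng) == 0) return(channel)  # no contrast to enhance
  nx <- max(2L, min(nrow(channel) %/% 8L, round(nrow(channel) / tile_size)))
  ny <- max(2L, min(ncol(channel) %/% 8L, round(ncol(channel) / tile_size)))
  scaled <- (channel - rng[1]) / diff(rng)
  # clahe needs dimensions divisible by the tile counts: pad by edge
  # replication, equalize, crop back
  dx <- nrow(scaled); dy <- ncol(scaled)
  px <- (nx - dx %% nx) %% nx
  py <- (ny - dy %% ny) %% ny
  padded <- scaled[c(seq_len(dx), rep(dx, px)), c(seq_len(dy), rep(dy, py))]
  out <- EBImage::imageData(EBImage::clahe(
    EBImage::Image(padded), nx = nx, ny = ny, bins = 256L,
    limit = max(1, clip_limit * 256), keep.range = TRUE))
  out[seq_len(dx), seq_len(dy)] * diff(rng) + rng[1]
}

# Otsu threshold on a 256-bin histogram spanning [0, max(x)]; covariant
# under multiplication of x by a positive constant.
otsu_threshold <- function(x, levels = 256L) {
  mx <- max(x)
  if (mx <= 0) return(0)
  EBImage::otsu(EBImage::Image(x), range = c(0, mx), levels = levels)
}

#' Binarize a two-channel whole mount into a trinary label map
#'
#' The tissue mask is the set of pixels whose summed red + green intensity
#' exceeds `tissue_min_intensity` times the Otsu auto-threshold of the sum
#' image. Within tissue, per-channel Otsu thresholds decide which channels
#' are "on"; a pixel is `GREEN` when the green channel is on and either
#' the red channel is off or green intensity strictly exceeds red, and
#' `RED` otherwise (exact ties go to red, deterministically). Pixels
#' outside the tissue mask are `NON_TISSUE`.
#'
#' All thresholds are computed on 256-bin histograms spanning `[0, max]`,
#' so the label map is invariant to rescaling both channels by a common
#' positive constant.
#'
#' @param image A `whole_mount_image` (channels raw or preprocessed with
#'   [subtract_background()] / [enhance_local_contrast()]).
#' @param tissue_min_intensity Multiplier on the sum-image auto-threshold
#'   defining the tissue mask.
#' @param threshold_method Auto-threshold method; `"otsu"` is currently
#'   the only implemented choice (matching ImageJ's default behaviour).
#' @return A [label_map()]. If no pixel passes the tissue threshold the
#'   map is all `NON_TISSUE`, carries attribute `degenerate = TRUE`, and a
#'   warning is raised.
#' @export
binarize <- function(image, tissue_min_intensity = 0.5,
                     threshold_method = c("otsu")) {
  stopifnot(inherits(image, "whole_mount_image"))
  threshold_method <- match.arg(threshold_method)
  check_positive(tissue_min_intensity, "tissue_min_intensity")

  red <- image$red
  green <- image$green
  if (!all(dim(red) == dim(green))) {
    stop_param("red and green channels must have identical shape.")
  }

  total <- red + green
  t_sum <- otsu_threshold(total)
  tissue <- total > tissue_min_intensity * t_sum

  labels <- matrix(LBL_NON_TISSUE, nrow(red), ncol(red))
  if (!any(tissue)) {
    warn("No pixel passed the tissue threshold; returning an all-non-tissue map.")
    out <- label_map(labels, image$pixel_size)
    attr(out, "degenerate") <- TRUE
    return(out)
  }

  t_red <- otsu_threshold(red)
  t_green <- otsu_threshold(green)
  green_on <- green > t_green
  red_on <- red > t_red
  is_green <- tissue & green_on & (!red_on | green > red)
  labels[tissue] <- LBL_RED
  labels[is_green] <- LBL_GREEN

  out <- label_map(labels, image$pixel_size)
  attr(out, "thresholds") <- c(sum = t_sum, red = t_red, green = t_green)
  out
}

#' Full preprocessing and binarization of a whole mount
#'
#' Applies the whole-mount macro stages in order — rolling-ball background
#' subtraction, CLAHE, auto-threshold binarization — to both channels.
#'
#' @inheritParams binarize
#' @inheritParams subtract_background
#' @inheritParams enhance_local_contrast
#' @param clahe Logical; apply CLAHE after background subtraction.
#' @return A [label_map()].
#' @export
process_whole_mount <- function(image, rolling_radius = 40, clahe = TRUE,
                                tile_size = 64, clip_limit = 0.01,
                                tissue_min_intensity = 0.5) {
  stopifnot(inherits(image, "whole_mount_image"))
  pre <- image
  pre$red <- subtract_background(image$red, rolling_radius)
  pre$green <- subtract_background(image$green, rolling_radius)
  if (clahe) {
    pre$red <- enhance_local_contrast(pre$red, tile_size, clip_limit)
    pre$green <- enhance_local_contrast(pre$green, tile_size, clip_limit)
  }
  binarize(pre, tissue_min_intensity = tissue_min_intensity)
}
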