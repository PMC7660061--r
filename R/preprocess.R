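# Projection-profile background removal.
#
# Endoscopy stills carry a dark, uninformative border around a bright tissue
# foreground. The per-row and per-column mean gray levels (projection
# profiles) separate the two cleanly: profile entries over the border sit
# near zero, entries over the foreground near the tissue brightness. The
# foreground is located by thresholding each profile at a fraction of its
# own maximum, which is robust to exposure differences between devices.

# BT.601 luma weights used for the gray-level conversion throughout.
.LUMA <- c(0.299, 0.587, 0.114)

# Accepts H x W x 3 arrays in [0, 1] (the package convention) or 0-255;
# returns the gray-level matrix on the 0-255 scale.
grayLevels <- function(image) {
  if (length(dim(image)) == 2L) {
    g <- image
  } else {
    if (dim(image)[3] < 3L) stop("image must have 3 channels (or be a matrix)")
    g <- .LUMA[1] * image[, , 1] + .LUMA[2] * image[, , 2] +
      .LUMA[3] * image[, , 3]
    if (is.null(dim(g))) g <- matrix(g, dim(image)[1], dim(image)[2])
  }
  if (max(g) <= 1) g <- g * 255
  g
}

#' Projection profiles of an image
#'
#' Converts the image to gray levels (BT.601 luma, 0-255 scale) and projects
#' it onto both axes: `rowProfile[i]` is the mean gray level of pixel row
#' `i`, `colProfile[j]` the mean of column `j`.
#'
#' @param image an H x W x 3 array (values in [0, 1] or 0-255) or an H x W
#'   gray-level matrix.
#' @return a list of class `ProjectionProfiles` with numeric vectors
#'   `rowProfile` (length H) and `colProfile` (length W), entries in
#'   [0, 255].
#' @examples
#' img <- array(128 / 255, c(4, 6, 3))
#' projectionProfiles(img)$colProfile
#' @export
projectionProfiles <- function(image) {
  d <- dim(image)
  if (is.null(d) || d[1] < 1L || d[2] < 1L || any(d == 0L))
    stop("image must be a non-empty array")
  g <- grayLevels(image)
  structure(list(rowProfile = rowMeans(g), colProfile = colMeans(g)),
            class = "ProjectionProfiles")
}

# threshold one profile: first through last index exceeding
# fraction * max(profile); NULL when nothing exceeds (all-zero profile)
profileSpan <- function(profile, thresholdFraction) {
  thr <- thresholdFraction * max(profile)
  hit <- which(profile > thr)
  if (length(hit) == 0L) return(NULL)
  c(first = hit[1L], last = hit[length(hit)])
}

#' Foreground bounds from projection profiles
#'
#' Thresholds each profile at `thresholdFraction` of its own maximum
#' (per-axis thresholds). The returned box spans, on each axis, the first
#' through last index whose profile value exceeds the threshold. If either
#' axis has no index above threshold (a fully dark frame), the full frame is
#' returned with `fallbackUsed = TRUE`.
#'
#' @param profiles a `ProjectionProfiles` object from
#'   [projectionProfiles()].
#' @param thresholdFraction relative threshold in (0, 1); default 0.10.
#' @return a list with `box` (a [cropBox()]) and `fallbackUsed` (logical).
#' @examples
#' p <- structure(list(rowProfile = c(0, 150, 150, 0),
#'                     colProfile = c(0, 0, 200, 200, 200, 200)),
#'                class = "ProjectionProfiles")
#' foregroundBounds(p, 0.1)$box
#' @export
foregroundBounds <- function(profiles, thresholdFraction = 0.10) {
  if (thresholdFraction <= 0 || thresholdFraction >= 1)
    stop("thresholdFraction must lie in (0, 1)")
  H <- length(profiles$rowProfile)
  W <- length(profiles$colProfile)
  rowSpan <- profileSpan(profiles$rowProfile, thresholdFraction)
  colSpan <- profileSpan(profiles$colProfile, thresholdFraction)
  if (is.null(rowSpan) || is.null(colSpan)) {
    return(list(box = cropBox(0L, H, 0L, W), fallbackUsed = TRUE))
  }
  # profile indices are 1-based; the box is 0-based half-open
  list(box = cropBox(rowSpan["first"] - 1L, rowSpan["last"],
                     colSpan["first"] - 1L, colSpan["last"]),
       fallbackUsed = FALSE)
}

# bilinear resize of an H x W x C array to side x side (EBImage backend)
bilinearResize <- function(image, side) {
  if (dim(image)[1] == side && dim(image)[2] == side) return(image)
  # EBImage uses (x, y) = (col, row) order, so transpose in and out
  img <- EBImage::Image(aperm(image, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(img, w = side, h = side, filter = "bilinear")
  aperm(EBImage::imageData(out), c(2, 1, 3))
}

#' Preprocess one frame for classification
#'
#' Removes the dark background (crop to [foregroundBounds()]), bilinearly
#' resizes the crop to `outSize` x `outSize`, and rescales intensities to
#' [0, 1]. Residual dark corners inside the crop are tolerated; the step
#' aims to remove the bulk of the uninformative border, not every dark
#' pixel.
#'
#' @param image an H x W x 3 array, values in [0, 1] or 0-255.
#' @param thresholdFraction relative profile threshold in (0, 1).
#' @param outSize output side length in pixels (224 for the paper-scale
#'   classifiers, 64 for the tiny profile).
#' @return a list with `image` (`outSize` x `outSize` x 3 array in [0, 1]),
#'   `box` (the crop box used) and `fallbackUsed`.
#' @examples
#' fr <- generateFrame(frameSpec(64, 64, label = 0, seed = 3))
#' out <- preprocessFrame(fr$image, outSize = 32)
#' dim(out$image)
#' @export
preprocessFrame <- function(image, thresholdFraction = 0.10, outSize = 224L) {
  if (max(image) > 1) image <- image / 255
  fb <- foregroundBounds(projectionProfiles(image), thresholdFraction)
  crop <- applyCrop(image, fb$box)
  out <- bilinearResize(crop, outSize)
  out <- pmin(pmax(out, 0), 1)
  list(image = out, box = fb$box, fallbackUsed = fb$fallbackUsed)
}

#' Map a box through crop-and-resize preprocessing
#'
#' Transforms a box given in original-frame coordinates (for example a
#' lesion annotation) into the coordinate system of the preprocessed frame:
#' the crop offset is subtracted and both axes are rescaled to the output
#' size. The result is clipped to the output bounds.
#'
#' @param box a [cropBox()] in original-frame coordinates.
#' @param crop the crop box applied by [preprocessFrame()].
#' @param outSize the preprocessed side length.
#' @return a [cropBox()] in preprocessed-frame coordinates.
#' @export
transformBox <- function(box, crop, outSize) {
  sy <- outSize / (crop$bottom - crop$top)
  sx <- outSize / (crop$right - crop$left)
  top <- max(0, floor((box$top - crop$top) * sy))
  bottom <- min(outSize, ceiling((box$bottom - crop$top) * sy))
  left <- max(0, floor((box$left - crop$left) * sx))
  right <- min(outSize, ceiling((box$right - crop$left) * sx))
  cropBox(top, max(bottom, top + 1), left, max(right, left + 1))
}

#' Preprocess a batch of frames into an input tensor
#'
#' Applies [preprocessFrame()] to each file and stacks the results into the
#' 4-D activation layout used by the classifiers.
#'
#' @param paths character vector of PNG paths.
#' @param thresholdFraction relative profile threshold.
#' @param outSize output side length.
#' @return an `outSize x outSize x 3 x N` array in [0, 1].
#' @export
preprocessBatch <- function(paths, thresholdFraction = 0.10, outSize = 64L) {
  n <- length(paths)
  x <- array(0, c(outSize, outSize, 3L, n))
  for (i in seq_len(n)) {
    img <- png::readPNG(paths[i])
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
    x[, , , i] <- preprocessFrame(img[, , 1:3, drop = FALSE],
                                  thresholdFraction, outSize)$image
  }
  x
}
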