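#' Construct a crop box
#'
#' A crop box uses 0-based, half-open pixel coordinates: rows `[top, bottom)`
#' and columns `[left, right)`. This is the coordinate convention used by the
#' background-removal step and by the synthetic generator's lesion boxes.
#'
#' @param top,bottom,left,right integer pixel indices with
#'   `0 <= top < bottom` and `0 <= left < right`.
#' @return a list of class `CropBox` with fields `top`, `bottom`, `left`,
#'   `right`.
#' @examples
#' cropBox(0, 64, 0, 64)
#' @export
cropBox <- function(top, bottom, left, right) {
  b <- list(top = as.integer(top), bottom = as.integer(bottom),
            left = as.integer(left), right = as.integer(right))
  if (b$top < 0L || b$left < 0L)
    stop("CropBox invariant violated: top and left must be >= 0")
  if (b$top >= b$bottom)
    stop("CropBox invariant violated: top < bottom required")
  if (b$left >= b$right)
    stop("CropBox invariant violated: left < right required")
  class(b) <- "CropBox"
  b
}

#' @export
print.CropBox <- function(x, ...) {
  cat(sprintf("CropBox rows [%d, %d) x cols [%d, %d)\n",
              x$top, x$bottom, x$left, x$right))
  invisible(x)
}

# box area in pixels
boxArea <- function(box) (box$bottom - box$top) * (box$right - box$left)

# does `outer` contain `inner` entirely?
boxContains <- function(outer, inner) {
  outer$top <= inner$top && outer$bottom >= inner$bottom &&
    outer$left <= inner$left && outer$right >= inner$right
}

# crop an H x W x C array with a CropBox (0-based half-open -> R indices)
applyCrop <- function(image, box) {
  image[(box$top + 1L):box$bottom, (box$left + 1L):box$right, , drop = FALSE]
}
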