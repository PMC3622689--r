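#' Discrete disk structuring element
#'
#' Pixel `(i, j)` (offsets from the center) belongs to the disk iff
#' `i^2 + j^2 <= r^2`, so results are bit-reproducible across platforms.
#'
#' @param radius Non-negative integer radius in pixels.
#' @return A `(2r+1) x (2r+1)` 0/1 matrix.
#' @export
disk_kernel <- function(radius) {
  r <- as.integer(radius)
  stopifnot(r >= 0L)
  off <- -r:r
  outer(off, off, function(a, b) as.integer(a * a + b * b <= r * r)) * 1
}

#' Remove thresholding speckle by morphological opening
#'
#' Erosion followed by dilation with a [disk_kernel()]. Out-of-bounds
#' pixels are ignored (erosion keeps a foreground pixel if every
#' in-bounds pixel under the element is foreground), so a full-frame
#' mask is invariant. Opening is anti-extensive (never adds pixels) and
#' idempotent; a radius of 0 is the identity. This is the "rough pass"
#' filter that removes the noisiest elements before any size-based
#' filtering, which makes choosing the minimum object size much easier.
#'
#' @param mask Logical matrix.
#' @param disk_radius Structuring element radius in pixels.
#' @return Filtered logical matrix.
#' @export
speckle_filter <- function(mask, disk_radius) {
  stopifnot(is.matrix(mask), disk_radius >= 0)
  if (disk_radius == 0) return(mask)
  k <- disk_kernel(disk_radius)
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  EBImage::dilate(EBImage::erode(m, k), k) > 0.5
}

#' Dilate a mask with a disk
#'
#' Used to construct the cytosolic ring around nuclei; same boundary
#' convention as [speckle_filter()].
#'
#' @inheritParams speckle_filter
#' @return Dilated logical matrix.
#' @export
dilate_mask <- function(mask, disk_radius) {
  stopifnot(is.matrix(mask), disk_radius >= 0)
  if (disk_radius == 0) return(mask)
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  EBImage::dilate(m, disk_kernel(disk_radius)) > 0.5
}
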