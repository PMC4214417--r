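# Plant segmentation from side-view colour images.
#
# Green vegetation on a uniform background is separated with the
# excess-green index ExG = 2G - R - B, thresholded either by Otsu's method
# on the ExG histogram or at a fixed value, followed by a small-component
# filter.  Holes inside retained components are deliberately left open:
# the projected area counts plant pixels only.

#' Excess-green index map
#'
#' @param image An [rgb_image()].
#' @return Numeric matrix `2G - R - B` (range `[-510, 510]`).
#' @export
excess_green <- function(image) {
  a <- unclass(image)
  2 * a[, , 2] - a[, , 1] - a[, , 3]
}

#' Segment a plant from a side-view colour image
#'
#' Thresholds the excess-green map and keeps connected components of at
#' least `min_object_px` pixels (8-connectivity).
#'
#' @param image An [rgb_image()].
#' @param min_object_px Minimum component size kept, default 64.
#' @param threshold_mode `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold ExG cut used when `threshold_mode = "fixed"`;
#'   pixels with ExG strictly above it are candidate foreground.
#' @return A [plant_mask()].
#' @export
segment_plant <- function(image, min_object_px = 64L,
                          threshold_mode = c("otsu", "fixed"),
                          fixed_threshold = 20) {
  threshold_mode <- match.arg(threshold_mode)
  if (min_object_px < 1L) stop("`min_object_px` must be >= 1")
  exg <- excess_green(image)
  if (max(exg) == min(exg))
    stop("no plant found: image has no greenness contrast")
  if (threshold_mode == "otsu") {
    # shift ExG into [0, 255] for the histogram threshold
    shifted <- floor((exg + 510) / 4)   # quantized to the histogram bins
    thr <- otsu_threshold(shifted)
    fg <- shifted > thr
  } else {
    fg <- exg > fixed_threshold
  }
  if (!any(fg)) stop("no plant found: zero foreground pixels")
  cc <- label_components(fg, connectivity = 8L)
  keep <- which(cc$sizes >= min_object_px)
  if (length(keep) == 0L) stop("no plant found: all components below size filter")
  plant_mask(matrix(cc$labels %in% keep, nrow(fg), ncol(fg)))
}

#' Projected area of a mask
#'
#' The raw trait of the imaging pipeline: the exact number of foreground
#' pixels in one view.
#'
#' @param mask A [plant_mask()].
#' @return Non-negative integer pixel count.
#' @export
projected_area <- function(mask) {
  sum(unclass(mask))
}

#' Plant height in millimetres
#'
#' Vertical extent of the foreground (inclusive row span) scaled by the
#' calibration.
#'
#' @param mask A [plant_mask()].
#' @param cal A [calibration()].
#' @return Height in mm.
#' @export
plant_height <- function(mask, cal) {
  rows <- which(rowSums(unclass(mask)) > 0)
  if (length(rows) == 0L) stop("empty mask")
  (max(rows) - min(rows) + 1L) * cal$mm_per_px
}
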