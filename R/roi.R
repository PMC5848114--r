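#' Region-of-interest specification
#'
#' ROIs are placed on a slice in pixel coordinates and sized in millimetres;
#' the extent is converted to pixels through the image pixel spacing at
#' evaluation time. A pixel belongs to the ROI when its centre lies inside
#' the region; rectangle edges use a half-open convention (left/top edge in,
#' right/bottom edge out) so that adjacent ROIs tile without overlap.
#'
#' @param shape `"rectangle"` or `"circle"`.
#' @param center ROI centre as 0-based `(row, col)` pixel coordinates
#'   (fractional values allowed).
#' @param extent_mm side length (rectangle) or diameter (circle), mm.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(shape = c("rectangle", "circle"), center, extent_mm) {
  shape <- match.arg(shape)
  stopifnot(length(center) == 2L, is.numeric(center), all(is.finite(center)))
  if (!is.numeric(extent_mm) || length(extent_mm) != 1L || extent_mm <= 0) {
    stop("extent_mm must be a single positive number")
  }
  structure(list(shape = shape, center = as.numeric(center),
                 extent_mm = as.numeric(extent_mm)),
            class = "roi_spec")
}

#' Rasterize an ROI to a pixel mask
#'
#' @param roi an [roi_spec()].
#' @param dim slice dimensions `c(nrow, ncol)`.
#' @param pixel_spacing `(row, col)` pixel spacing in mm.
#' @return Logical matrix of the slice dimensions.
#' @export
roi_mask <- function(roi, dim, pixel_spacing) {
  stopifnot(inherits(roi, "roi_spec"), length(dim) == 2L,
            length(pixel_spacing) == 2L, all(pixel_spacing > 0))
  # pixel centres in mm; 0-based pixel i has centre (i + 0.5) * spacing
  y <- (seq_len(dim[1]) - 0.5) * pixel_spacing[1]
  x <- (seq_len(dim[2]) - 0.5) * pixel_spacing[2]
  cy <- (roi$center[1] + 0.5) * pixel_spacing[1]
  cx <- (roi$center[2] + 0.5) * pixel_spacing[2]
  h <- roi$extent_mm / 2
  if (roi$shape == "rectangle") {
    lo_y <- cy - h; hi_y <- cy + h
    lo_x <- cx - h; hi_x <- cx + h
    if (lo_y < 0 || lo_x < 0 || hi_y > dim[1] * pixel_spacing[1] ||
        hi_x > dim[2] * pixel_spacing[2]) {
      stop(sprintf(
        "ROI [%.2f, %.2f] x [%.2f, %.2f] mm extends outside the %.2f x %.2f mm slice",
        lo_y, hi_y, lo_x, hi_x,
        dim[1] * pixel_spacing[1], dim[2] * pixel_spacing[2]))
    }
    rows <- y >= lo_y & y < hi_y
    cols <- x >= lo_x & x < hi_x
    outer(rows, cols, `&`)
  } else {
    if (cy - h < 0 || cx - h < 0 || cy + h > dim[1] * pixel_spacing[1] ||
        cx + h > dim[2] * pixel_spacing[2]) {
      stop(sprintf(
        "circular ROI centre (%.2f, %.2f) mm radius %.2f mm extends outside the slice",
        cy, cx, h))
    }
    outer((y - cy)^2, (x - cx)^2, `+`) <= h^2
  }
}

#' ROI statistics on a slice
#'
#' Mean and sample standard deviation (n - 1 denominator) of the pixels
#' whose centres lie inside the ROI. This is the statistic used to read off
#' `ctn_mar` and `ctn_cor` from calibration scans.
#'
#' @param image a [ct_image()] (a 2D slice) or a numeric matrix.
#' @param roi an [roi_spec()].
#' @param pixel_spacing required when `image` is a bare matrix.
#' @return An object of class `roi_stats`: list with `mean` (HU), `sd` (HU)
#'   and `n_pixels`.
#' @export
roi_stats <- function(image, roi, pixel_spacing = NULL) {
  if (inherits(image, "ct_image")) {
    pixel_spacing <- image$pixel_spacing
    mat <- image$voxels
    if (length(dim(mat)) == 3L) {
      if (dim(mat)[3] != 1L) stop("roi_stats expects a single slice")
      mat <- mat[, , 1L]
    }
  } else {
    mat <- image
    if (is.null(pixel_spacing)) stop("pixel_spacing required for a bare matrix")
  }
  m <- roi_mask(roi, dim(mat), pixel_spacing)
  vals <- mat[m]
  if (length(vals) < 1L) stop("ROI contains no pixel centres")
  structure(list(mean = mean(vals),
                 sd = if (length(vals) > 1L) stats::sd(vals) else 0,
                 n_pixels = length(vals)),
            class = "roi_stats")
}
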