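#' CT image container
#'
#' Holds a 2D slice or 3D volume of CT numbers (HU) together with the
#' geometry and acquisition metadata the analysis needs: pixel spacing,
#' slice thickness, tube voltage and an orientation label. Coordinates are
#' 0-based `(row, col[, slice])` pixel indices throughout the package.
#'
#' @param voxels numeric matrix (2D) or 3D array, HU; must be finite.
#' @param pixel_spacing `(row, col)` spacing in mm, > 0.
#' @param slice_thickness slice thickness in mm, > 0.
#' @param kvp tube voltage, kVp.
#' @param orientation free-text orientation label (e.g. `"coronal"`).
#' @param provenance source path or generator description (list or string).
#' @return An object of class `ct_image`.
#' @export
ct_image <- function(voxels, pixel_spacing, slice_thickness = 1, kvp = NA_integer_,
                     orientation = "axial", provenance = NULL) {
  stopifnot(is.numeric(voxels))
  nd <- length(dim(voxels))
  if (nd == 0L) stop("voxels must be a matrix or 3D array")
  if (!nd %in% c(2L, 3L)) stop("voxels must be 2D or 3D, got ", nd, " dims")
  if (!all(is.finite(voxels))) stop("voxels must be finite")
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  stopifnot(length(pixel_spacing) == 2L, all(pixel_spacing > 0),
            slice_thickness > 0)
  structure(list(voxels = voxels,
                 pixel_spacing = as.numeric(pixel_spacing),
                 slice_thickness = as.numeric(slice_thickness),
                 kvp = if (is.na(kvp)) NA_integer_ else as.integer(kvp),
                 orientation = orientation,
                 provenance = provenance),
            class = "ct_image")
}

#' @export
print.ct_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat("<ct_image> ", paste(d, collapse = " x "), " voxels @ ",
      paste(x$pixel_spacing, collapse = " x "), " mm, thickness ",
      x$slice_thickness, " mm, ", x$kvp, " kVp, ", x$orientation, "\n",
      sep = "")
  cat("  HU range [", round(min(x$voxels), 1), ", ", round(max(x$voxels), 1),
      "]\n", sep = "")
  invisible(x)
}

#' Extract a slice from a volume as a 2D ct_image
#'
#' @param image a [ct_image()].
#' @param slice 1-based slice index (third array dimension).
#' @return A 2D `ct_image`.
#' @export
ct_slice <- function(image, slice) {
  stopifnot(inherits(image, "ct_image"))
  v <- image$voxels
  if (length(dim(v)) == 2L) {
    if (slice != 1L) stop("2D image has a single slice")
    return(image)
  }
  if (slice < 1L || slice > dim(v)[3]) {
    stop("slice ", slice, " out of range 1..", dim(v)[3])
  }
  out <- image
  out$voxels <- v[, , slice]
  out
}

# ---- portable single-file text format ----------------------------------
#
# Line 1: a JSON header with geometry/acquisition metadata and the array
# dimensions; remaining lines: voxel values, one image row per line
# (slices concatenated in order for 3D). Plain text, byte-reproducible,
# independent of any DICOM dialect.

#' Write / read a CT image in the portable text format
#'
#' A single-file container: a one-line JSON header (dimensions, pixel
#' spacing, slice thickness, kVp, orientation, provenance, format version)
#' followed by the voxel values in row-major text, one image row per line,
#' slices in order. Values are written with full double precision
#' (`digits = 17`), so a write/read round trip reproduces the HU exactly.
#'
#' @param image a [ct_image()].
#' @param path output file path (conventionally `.ctt`).
#' @return `write_ct()` returns `path` invisibly; `read_ct()` a [ct_image()].
#' @export
write_ct <- function(image, path) {
  stopifnot(inherits(image, "ct_image"))
  d <- dim(image$voxels)
  header <- jsonlite::toJSON(
    list(format = "qctbone-ct", version = 1L, dim = d,
         pixel_spacing = image$pixel_spacing,
         slice_thickness = image$slice_thickness,
         kvp = image$kvp, orientation = image$orientation,
         provenance = image$provenance),
    auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(as.character(header), con)
  nslice <- if (length(d) == 3L) d[3] else 1L
  for (s in seq_len(nslice)) {
    m <- if (length(d) == 3L) image$voxels[, , s] else image$voxels
    # one text line per image row
    writeLines(apply(format(m, digits = 17, trim = TRUE, scientific = FALSE),
                     1L, paste, collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_ct
#' @export
read_ct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("file ", path, " is not a portable CT image")
  header <- jsonlite::fromJSON(lines[1L])
  if (is.null(header$format) || header$format != "qctbone-ct") {
    stop("file ", path, " lacks the qctbone-ct header")
  }
  if (is.null(header$pixel_spacing)) {
    stop("header of ", path, " is missing required attribute: pixel_spacing")
  }
  d <- as.integer(header$dim)
  nrow_total <- if (length(d) == 3L) d[1] * d[3] else d[1]
  if (length(lines) - 1L != nrow_total) {
    stop("expected ", nrow_total, " voxel rows in ", path, ", found ",
         length(lines) - 1L)
  }
  vals <- scan(text = lines[-1L], what = numeric(), quiet = TRUE)
  if (length(d) == 3L) {
    vox <- array(NA_real_, d)
    per <- d[1]
    for (s in seq_len(d[3])) {
      block <- lines[1L + (s - 1L) * per + seq_len(per)]
      vox[, , s] <- matrix(scan(text = block, what = numeric(), quiet = TRUE),
                           nrow = d[1], ncol = d[2], byrow = TRUE)
    }
  } else {
    vox <- matrix(vals, nrow = d[1], ncol = d[2], byrow = TRUE)
  }
  ct_image(vox,
           pixel_spacing = as.numeric(header$pixel_spacing),
           slice_thickness = as.numeric(header$slice_thickness),
           kvp = if (is.null(header$kvp) || is.na(header$kvp)) NA_integer_ else header$kvp,
           orientation = header$orientation,
           provenance = header$provenance)
}

#' Sample a line profile across an image
#'
#' Bilinear interpolation at `n_samples` equispaced points on the segment
#' from `start` to `end` (0-based `(row, col)` pixel coordinates). Positions
#' are reported in mm from the start point using the pixel spacing; this is
#' the tool behind the across-the-vials and across-the-femoral-neck
#' profiles.
#'
#' @param image a [ct_image()] 2D slice, a `density_map` (its vBMD plane),
#'   or a bare matrix (then `pixel_spacing` is required).
#' @param start,end endpoints, 0-based `(row, col)` pixel coordinates.
#' @param n_samples number of sample points (>= 2).
#' @param pixel_spacing `(row, col)` mm; taken from `image` when available.
#' @return An object of class `line_profile`: data frame with `position_mm`
#'   (strictly increasing from 0) and `value`.
#' @export
extract_profile <- function(image, start, end, n_samples = 200,
                            pixel_spacing = NULL) {
  if (inherits(image, "ct_image")) {
    pixel_spacing <- image$pixel_spacing
    mat <- image$voxels
  } else if (inherits(image, "density_map")) {
    mat <- image$vbmd
    if (is.null(pixel_spacing)) stop("pixel_spacing required for a density_map")
  } else {
    mat <- image
    if (is.null(pixel_spacing)) stop("pixel_spacing required for a bare matrix")
  }
  if (length(dim(mat)) != 2L) stop("extract_profile expects a single 2D slice")
  stopifnot(length(start) == 2L, length(end) == 2L, n_samples >= 2L)
  if (all(start == end)) stop("profile endpoints must be distinct")
  d <- dim(mat)
  for (p in list(start, end)) {
    if (p[1] < 0 || p[1] > d[1] - 1 || p[2] < 0 || p[2] > d[2] - 1) {
      stop("profile endpoint (", p[1], ", ", p[2], ") outside image 0..",
           d[1] - 1, " x 0..", d[2] - 1)
    }
  }
  t <- seq(0, 1, length.out = n_samples)
  rr <- start[1] + t * (end[1] - start[1])
  cc <- start[2] + t * (end[2] - start[2])
  # bilinear interpolation on the 0-based grid
  r0 <- pmin(pmax(floor(rr), 0), d[1] - 2); r1 <- r0 + 1
  c0 <- pmin(pmax(floor(cc), 0), d[2] - 2); c1 <- c0 + 1
  fr <- rr - r0; fc <- cc - c0
  v00 <- mat[cbind(r0 + 1, c0 + 1)]; v01 <- mat[cbind(r0 + 1, c1 + 1)]
  v10 <- mat[cbind(r1 + 1, c0 + 1)]; v11 <- mat[cbind(r1 + 1, c1 + 1)]
  vals <- (1 - fr) * ((1 - fc) * v00 + fc * v01) +
          fr * ((1 - fc) * v10 + fc * v11)
  seg_mm <- sqrt(((end[1] - start[1]) * pixel_spacing[1])^2 +
                 ((end[2] - start[2]) * pixel_spacing[2])^2)
  out <- data.frame(position_mm = t * seg_mm, value = vals)
  class(out) <- c("line_profile", "data.frame")
  attr(out, "endpoints") <- list(start = start, end = end)
  out
}
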