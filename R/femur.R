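# Femoral-neck protocol: bone segmentation at a fixed HU threshold,
# selection of the maximum-neck-area coronal slice plus its neighbours,
# and conversion of the VOI mean CT number to a single vBMD.

#' Segment bone on a CT slice
#'
#' Thresholds the slice at `threshold` HU (default 250, the standard
#' bone/soft-tissue cut), keeps the largest connected component (optionally
#' restricted to a user ROI), and fills enclosed holes so that low-HU
#' marrow and nonosseous voids inside the bone contour belong to the mask.
#' Filling matters: a femoral-neck vBMD must reflect nonosseous areas, and
#' averaging only supra-threshold pixels would bias it upward.
#'
#' @param slice a 2D [ct_image()] or numeric matrix, HU.
#' @param threshold segmentation threshold, HU.
#' @param roi optional [roi_spec()] restricting the candidate region.
#' @param pixel_spacing needed when `slice` is a bare matrix and `roi` is
#'   given.
#' @param fill fill enclosed holes? Default `TRUE`. Setting `FALSE` gives a
#'   supra-threshold-only mask for sensitivity analyses.
#' @return Logical matrix (the filled bone mask).
#' @export
segment_bone <- function(slice, threshold = 250, roi = NULL,
                         pixel_spacing = NULL, fill = TRUE) {
  if (inherits(slice, "ct_image")) {
    pixel_spacing <- slice$pixel_spacing
    mat <- slice$voxels
    if (length(dim(mat)) == 3L) stop("segment_bone expects a single slice")
  } else {
    mat <- slice
  }
  if (!all(is.finite(mat))) stop("slice must be finite")
  m <- mat >= threshold
  if (!is.null(roi)) {
    if (is.null(pixel_spacing)) stop("pixel_spacing required to place the ROI")
    m <- m & roi_mask(roi, dim(mat), pixel_spacing)
  }
  if (!any(m)) {
    stop("no pixels above the ", threshold,
         " HU threshold: no bone in this slice/ROI")
  }
  lab <- EBImage::bwlabel(m)
  counts <- tabulate(lab[lab > 0])
  keep <- lab == which.max(counts)
  if (fill) keep <- EBImage::fillHull(keep) > 0
  matrix(as.logical(keep), nrow = nrow(mat))
}

#' Select the maximum-neck-area slice and its neighbours
#'
#' Computes the segmented-and-filled bone area (mm^2) inside the neck ROI
#' for every slice of the volume and returns the slice with the maximum
#' area together with its two adjacent slices. Ties go to the lower slice
#' index (flagged); an argmax at the volume boundary returns the two
#' available neighbours and sets the boundary flag.
#'
#' @param volume a 3D [ct_image()].
#' @param neck_roi an [roi_spec()] (applied to every slice) or a list of
#'   one spec per slice.
#' @param threshold bone segmentation threshold, HU.
#' @return List with `slices` (selected indices), `best` (argmax index),
#'   `areas_mm2` (per-slice), `tie` and `boundary` flags.
#' @export
select_voi_slices <- function(volume, neck_roi, threshold = 250) {
  stopifnot(inherits(volume, "ct_image"))
  d <- dim(volume$voxels)
  if (length(d) != 3L || d[3] < 3L) stop("volume must have at least 3 slices")
  n <- d[3]
  rois <- if (inherits(neck_roi, "roi_spec")) rep(list(neck_roi), n) else neck_roi
  stopifnot(length(rois) == n)
  px_area <- prod(volume$pixel_spacing)
  areas <- vapply(seq_len(n), function(k) {
    sl <- volume$voxels[, , k]
    mask <- tryCatch(segment_bone(sl, threshold), error = function(e) NULL)
    if (is.null(mask)) return(0)
    sum(mask & roi_mask(rois[[k]], dim(sl), volume$pixel_spacing)) * px_area
  }, numeric(1))
  best <- which(areas == max(areas))
  tie <- length(best) > 1L
  best <- min(best)
  lo <- max(1L, best - 1L); hi <- min(n, best + 1L)
  list(slices = lo:hi, best = best, areas_mm2 = areas,
       tie = tie, boundary = (best == 1L || best == n))
}

#' Femoral-neck vBMD from a CT volume
#'
#' The full clinical protocol: per-slice bone segmentation and hole filling
#' at `threshold` HU, selection of the maximum-neck-area slice plus its two
#' neighbours, averaging the CT numbers over the union of the filled bone
#' masks restricted to the neck ROI, conversion of that mean to vBMD with
#' the two-compartment inversion, and ACR classification. Because the
#' inversion is affine, converting the VOI mean equals averaging a
#' converted map over the VOI.
#'
#' @inheritParams select_voi_slices
#' @param calib a [calibration_table()] or [calibration_entry()].
#' @param kvp calibration selector; defaults to the volume's kVp metadata.
#' @param bone_only average only supra-threshold pixels (no hole filling);
#'   default `FALSE` (filled contour, voids included).
#' @return An object of class `voi_result`: list with `selected_slices`,
#'   `voi_mask` (logical array over the selected slices), `mean_ctn` (HU),
#'   `bvf`, `vbmd` (g/cm^3), `n_voxels`, `diagnostic`
#'   (see [classify_acr()]), `areas_mm2`, and `flags` (tie/boundary).
#' @export
femoral_neck_vbmd <- function(volume, neck_roi, calib, kvp = NULL,
                              threshold = 250, bone_only = FALSE) {
  stopifnot(inherits(volume, "ct_image"))
  if (is.null(kvp)) kvp <- volume$kvp
  entry <- calibration_for(calib, kvp)
  sel <- select_voi_slices(volume, neck_roi, threshold)
  d <- dim(volume$voxels)
  rois <- if (inherits(neck_roi, "roi_spec")) rep(list(neck_roi), d[3]) else neck_roi
  vals <- numeric(0)
  voi_mask <- array(FALSE, dim = c(d[1], d[2], length(sel$slices)))
  for (i in seq_along(sel$slices)) {
    k <- sel$slices[i]
    sl <- volume$voxels[, , k]
    bone <- segment_bone(sl, threshold, fill = !bone_only)
    m <- bone & roi_mask(rois[[k]], dim(sl), volume$pixel_spacing)
    voi_mask[, , i] <- m
    vals <- c(vals, sl[m])
  }
  if (length(vals) < 1L) stop("VOI contains no bone voxels")
  mean_ctn <- mean(vals)
  dm <- ctn_to_bvf_vbmd(mean_ctn, entry)
  structure(list(selected_slices = sel$slices,
                 voi_mask = voi_mask,
                 mean_ctn = mean_ctn,
                 bvf = dm$bvf, vbmd = dm$vbmd,
                 n_voxels = length(vals),
                 diagnostic = classify_acr(max(dm$vbmd, 0)),
                 areas_mm2 = sel$areas_mm2,
                 flags = list(tie = sel$tie, boundary = sel$boundary),
                 calibration = entry),
            class = "voi_result")
}

#' @export
print.voi_result <- function(x, ...) {
  cat("<voi_result> slices ", paste(x$selected_slices, collapse = ", "),
      " (", x$n_voxels, " voxels)\n", sep = "")
  cat("  mean CTN ", round(x$mean_ctn, 1), " HU -> vBMD ",
      round(x$vbmd, 4), " g/cm^3 (", round(x$vbmd * 1000, 1), " mg/cm^3), ",
      as.character(x$diagnostic$label), "\n", sep = "")
  if (x$flags$tie) cat("  note: tie in maximum neck area, lower slice chosen\n")
  if (x$flags$boundary) cat("  note: argmax at volume boundary, fewer neighbours\n")
  invisible(x)
}
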