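#' Volume fraction of a material in a two-material mixture
#'
#' Inverts the linearity of CT numbers in the component volume fractions.
#' Writing the mixture attenuation as a volume-weighted sum of the two
#' component attenuations, the CT-number definition gives
#'
#' \deqn{v_a = \frac{(CTN_{mix}/1000 + 1) - (CTN_b/1000 + 1)}
#'                  {(CTN_a/1000 + 1) - (CTN_b/1000 + 1)}
#'           = \frac{CTN_{mix} - CTN_b}{CTN_a - CTN_b},}
#'
#' the /1000 + 1 rescalings cancelling exactly. The raw fraction is
#' returned unclamped: values outside \[0, 1\] signal a voxel outside the
#' two-compartment assumption (e.g. denser than the calibration phantom)
#' and are the caller's to handle.
#'
#' @param ctn_mix CT number(s) of the mixture, HU (vectorized).
#' @param ctn_a,ctn_b CT numbers of pure materials a and b, HU.
#' @return Volume fraction(s) of material a, dimensionless.
#' @export
volume_fraction <- function(ctn_mix, ctn_a, ctn_b) {
  stopifnot(is.numeric(ctn_mix), is.numeric(ctn_a), is.numeric(ctn_b),
            length(ctn_a) == 1L, length(ctn_b) == 1L)
  if (!all(is.finite(ctn_mix)) || !is.finite(ctn_a) || !is.finite(ctn_b)) {
    stop("CT numbers must be finite")
  }
  if (ctn_a == ctn_b) {
    stop("degenerate calibration: materials a and b have identical CT number (",
         ctn_a, " HU); the mixture fraction is undefined")
  }
  (ctn_mix - ctn_b) / (ctn_a - ctn_b)
}

#' Weight fraction from volume fraction and densities
#'
#' \eqn{w_a = v_a \rho_a / \rho_{mix}}.
#'
#' @param v_a volume fraction(s) of material a.
#' @param rho_a density of material a, g/cm^3 (> 0).
#' @param rho_mix density of the mixture, g/cm^3 (> 0).
#' @return Weight fraction(s) of material a.
#' @export
weight_fraction <- function(v_a, rho_a, rho_mix) {
  if (!is.numeric(rho_a) || any(rho_a <= 0)) stop("rho_a must be positive")
  if (!is.numeric(rho_mix) || any(rho_mix <= 0)) stop("rho_mix must be positive")
  v_a * rho_a / rho_mix
}

#' Convert CT numbers to BVF and vBMD
#'
#' The central inversion of the two-compartment model. Each voxel is modelled
#' as a mixture of cortical-bone-equivalent material and marrow-equivalent
#' material (water), so its bone volume fraction is
#' \deqn{BVF = \frac{CTN_{mix} - CTN_{mar}}{CTN_{cor} - CTN_{mar}},
#'       \qquad vBMD = BVF \cdot \rho_{cor},}
#' with the reference CT numbers and \eqn{\rho_{cor}} taken from the per-kVp
#' calibration. The map is affine and element-wise, so converting a ROI mean
#' equals the mean of the converted voxels.
#'
#' By default raw BVF values are reported even outside \[0, 1\]: structures
#' denser than the calibration phantom (e.g. a 0.800 g/cm^3 cortical wall
#' against a 0.533 g/cm^3 phantom) legitimately map to BVF > 1, and clamping
#' them would hide the violated model assumption. With `clamp = TRUE` values
#' are clamped into \[0, 1\] and the affected voxels recorded in
#' `clamped_mask`.
#'
#' @param ctn_mix CT number(s), HU: scalar, vector, matrix or 3D array, or a
#'   [ct_image()] (its `kvp` metadata then selects the calibration entry).
#' @param calib a [calibration_entry()] or [calibration_table()].
#' @param kvp tube voltage used to select the entry when `calib` is a table
#'   and `ctn_mix` carries no kVp metadata.
#' @param clamp clamp BVF into \[0, 1\]? Default `FALSE`.
#' @return An object of class `density_map`: list with `bvf` (dimensionless),
#'   `vbmd` (g/cm^3), `clamped_mask` (logical, same shape), and `calibration`
#'   (the entry used). Array inputs keep their dimensions.
#' @export
ctn_to_bvf_vbmd <- function(ctn_mix, calib, kvp = NULL, clamp = FALSE) {
  if (inherits(ctn_mix, "ct_image")) {
    if (is.null(kvp)) kvp <- ctn_mix$kvp
    ctn_mix <- ctn_mix$voxels
  }
  entry <- calibration_for(calib, kvp)
  denom <- entry$ctn_cor - entry$ctn_mar   # > 0 by construction
  bvf <- (ctn_mix - entry$ctn_mar) / denom
  clamped <- bvf < 0 | bvf > 1
  if (clamp) bvf <- pmin(pmax(bvf, 0), 1)
  vbmd <- bvf * entry$rho_cor
  if (!is.null(dim(ctn_mix))) {
    dim(bvf) <- dim(vbmd) <- dim(clamped) <- dim(ctn_mix)
  }
  structure(list(bvf = bvf, vbmd = vbmd, clamped_mask = clamped,
                 calibration = entry, clamp = clamp),
            class = "density_map")
}

#' Forward CT number for a nominal vBMD
#'
#' Convenience inverse of [ctn_to_bvf_vbmd()]: the CT number a voxel of the
#' given vBMD would have under a calibration entry,
#' \eqn{CTN = (vBMD/\rho_{cor})(CTN_{cor} - CTN_{mar}) + CTN_{mar}}.
#'
#' @param vbmd nominal vBMD, g/cm^3 (vectorized).
#' @inheritParams ctn_to_bvf_vbmd
#' @return CT number(s), HU.
#' @export
vbmd_to_ctn <- function(vbmd, calib, kvp = NULL) {
  entry <- calibration_for(calib, kvp)
  (vbmd / entry$rho_cor) * (entry$ctn_cor - entry$ctn_mar) + entry$ctn_mar
}

#' ACR diagnostic classification of a vBMD value
#'
#' Applies the American College of Radiology quantitative-CT cut-offs:
#' osteoporosis below 80 mg/cm^3, osteopenia in the closed interval
#' \[80, 120\] mg/cm^3, normal above. Input is in g/cm^3 (the package's
#' canonical unit) and converted by an exact factor 1000.
#'
#' @param vbmd vBMD value(s), g/cm^3, non-negative.
#' @return A data frame of class `diagnostic_class` with columns
#'   `vbmd_mg_cm3` and `label` (factor with levels `normal`, `osteopenia`,
#'   `osteoporosis`).
#' @export
classify_acr <- function(vbmd) {
  if (!is.numeric(vbmd) || any(!is.finite(vbmd))) stop("vbmd must be finite")
  if (any(vbmd < 0)) stop("vbmd must be non-negative (got ", min(vbmd), ")")
  mg <- vbmd * 1000
  label <- ifelse(mg < 80, "osteoporosis", ifelse(mg <= 120, "osteopenia", "normal"))
  out <- data.frame(
    vbmd_mg_cm3 = mg,
    label = factor(label, levels = c("normal", "osteopenia", "osteoporosis"))
  )
  class(out) <- c("diagnostic_class", "data.frame")
  out
}

#' @export
print.density_map <- function(x, ...) {
  n <- length(x$bvf)
  cat("<density_map> ", n, " voxel(s), ",
      if (!is.null(dim(x$bvf))) paste(dim(x$bvf), collapse = " x ") else "scalar/vector",
      "\n", sep = "")
  cat("  calibration: ", x$calibration$kvp, " kVp (ctn_mar=",
      x$calibration$ctn_mar, ", ctn_cor=", x$calibration$ctn_cor,
      ", rho_cor=", x$calibration$rho_cor, " g/cm^3)\n", sep = "")
  cat("  vBMD range: [", signif(min(x$vbmd), 4), ", ", signif(max(x$vbmd), 4),
      "] g/cm^3; clamp=", x$clamp, "; ", sum(x$clamped_mask),
      " voxel(s) outside [0,1]\n", sep = "")
  invisible(x)
}
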