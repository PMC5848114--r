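#' Per-kVp calibration table for the two-compartment model
#'
#' A calibration table holds, for each tube voltage, the reference CT numbers
#' of the two compartments: `ctn_mar`, the mean CT number of the bone-marrow
#' surrogate (a water vial), and `ctn_cor`, the mean CT number of the
#' cortical-bone-equivalent phantom, together with their ROI standard
#' deviations and the mineral-equivalent density `rho_cor` (g/cm^3) of the
#' cortical calibration phantom. These are the parameters of the linear
#' inversion performed by [ctn_to_bvf_vbmd()].
#'
#' `rho_cor` is the K2HPO4 mass per solution volume of the calibration
#' phantom (its mineral-equivalent density), not its physical mass density;
#' it is the factor that turns a bone volume fraction into a vBMD.
#'
#' @param entries a list of entries created by [calibration_entry()].
#' @return An object of class `calibration_table`: a data frame with one row
#'   per tube voltage and columns `kvp`, `ctn_mar`, `ctn_mar_sd`, `ctn_cor`,
#'   `ctn_cor_sd`, `rho_cor`.
#' @seealso [default_calibration()], [calibration_entry()],
#'   [read_calibration()], [write_calibration()]
#' @export
calibration_table <- function(entries) {
  stopifnot(is.list(entries), length(entries) >= 1L)
  rows <- lapply(entries, function(e) {
    stopifnot(inherits(e, "calibration_entry"))
    as.data.frame(unclass(e))
  })
  tab <- do.call(rbind, rows)
  if (anyDuplicated(tab$kvp)) {
    stop("duplicate kVp entries in calibration table: ",
         paste(tab$kvp[duplicated(tab$kvp)], collapse = ", "))
  }
  tab <- tab[order(tab$kvp), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("calibration_table", "data.frame")
  tab
}

#' Single calibration entry
#'
#' @param kvp tube voltage in kVp (integer-valued).
#' @param ctn_mar mean CT number of the marrow surrogate (water), HU.
#' @param ctn_cor mean CT number of the cortical-equivalent phantom, HU.
#' @param rho_cor mineral-equivalent density of the cortical phantom, g/cm^3.
#' @param ctn_mar_sd,ctn_cor_sd ROI standard deviations, HU (>= 0).
#' @return An object of class `calibration_entry`.
#' @export
calibration_entry <- function(kvp, ctn_mar, ctn_cor, rho_cor,
                              ctn_mar_sd = 0, ctn_cor_sd = 0) {
  kvp <- as.integer(kvp)
  vals <- c(ctn_mar, ctn_cor, rho_cor, ctn_mar_sd, ctn_cor_sd)
  if (any(!is.finite(vals))) stop("calibration values must be finite")
  if (ctn_cor <= ctn_mar) {
    stop("degenerate calibration: ctn_cor (", ctn_cor,
         ") must exceed ctn_mar (", ctn_mar, ")")
  }
  if (rho_cor <= 0) stop("rho_cor must be positive, got ", rho_cor)
  if (ctn_mar_sd < 0 || ctn_cor_sd < 0) stop("ROI SDs must be non-negative")
  structure(
    list(kvp = kvp, ctn_mar = ctn_mar, ctn_mar_sd = ctn_mar_sd,
         ctn_cor = ctn_cor, ctn_cor_sd = ctn_cor_sd, rho_cor = rho_cor),
    class = "calibration_entry"
  )
}

#' Built-in scanner calibration
#'
#' Reference CT numbers of the water vial and the 0.533 g/cm^3
#' cortical-bone-equivalent K2HPO4 phantom measured at 80, 100 and 120 kVp:
#' water -11.1 +/- 30.3, 2.1 +/- 23.7 and 8.7 +/- 13.8 HU; cortical phantom
#' 982.2 +/- 41.4, 830.0 +/- 27.2 and 739.5 +/- 16.4 HU.
#'
#' @return A [calibration_table()] with entries at 80, 100 and 120 kVp.
#' @export
default_calibration <- function() {
  calibration_table(list(
    calibration_entry(80,  -11.1, 982.2, 0.533, ctn_mar_sd = 30.3, ctn_cor_sd = 41.4),
    calibration_entry(100,   2.1, 830.0, 0.533, ctn_mar_sd = 23.7, ctn_cor_sd = 27.2),
    calibration_entry(120,   8.7, 739.5, 0.533, ctn_mar_sd = 13.8, ctn_cor_sd = 16.4)
  ))
}

#' Look up the calibration entry for a tube voltage
#'
#' @param calib a [calibration_table()] or a single [calibration_entry()].
#' @param kvp tube voltage to look up; ignored when `calib` is already an
#'   entry.
#' @return A `calibration_entry`.
#' @export
calibration_for <- function(calib, kvp = NULL) {
  if (inherits(calib, "calibration_entry")) return(calib)
  stopifnot(inherits(calib, "calibration_table"))
  if (is.null(kvp)) stop("kvp must be given when calib is a table")
  i <- match(as.integer(kvp), calib$kvp)
  if (is.na(i)) {
    stop("no calibration entry for ", kvp, " kVp; available: ",
         paste(calib$kvp, collapse = ", "))
  }
  calibration_entry(calib$kvp[i], calib$ctn_mar[i], calib$ctn_cor[i],
                    calib$rho_cor[i], calib$ctn_mar_sd[i], calib$ctn_cor_sd[i])
}

#' Build a calibration entry from ROI statistics
#'
#' Takes the ROI mean/SD of a water vial scan and of the cortical-equivalent
#' phantom scan (see [roi_stats()]) and assembles the calibration entry used
#' by the inversion. The means become `ctn_mar` and `ctn_cor`.
#'
#' @param water_stats,cortical_stats `roi_stats` objects (fields `mean`,
#'   `sd`, `n_pixels`).
#' @param rho_cor mineral-equivalent density of the cortical phantom, g/cm^3.
#' @param kvp tube voltage of the calibration scans.
#' @return A [calibration_entry()].
#' @export
build_calibration <- function(water_stats, cortical_stats, rho_cor, kvp) {
  stopifnot(inherits(water_stats, "roi_stats"),
            inherits(cortical_stats, "roi_stats"))
  if (cortical_stats$mean <= water_stats$mean) {
    stop("inverted or degenerate calibration: cortical ROI mean (",
         cortical_stats$mean, " HU) does not exceed water ROI mean (",
         water_stats$mean, " HU)")
  }
  calibration_entry(kvp, water_stats$mean, cortical_stats$mean, rho_cor,
                    ctn_mar_sd = water_stats$sd, ctn_cor_sd = cortical_stats$sd)
}

#' Read / write a calibration table as a YAML config
#'
#' The file holds one block per tube voltage under a top-level `calibration`
#' key, e.g.
#' ```yaml
#' calibration:
#' - kvp: 120
#'   ctn_mar: 8.7
#'   ctn_mar_sd: 13.8
#'   ctn_cor: 739.5
#'   ctn_cor_sd: 16.4
#'   rho_cor: 0.533
#' ```
#'
#' @param path file path.
#' @return `read_calibration()` returns a [calibration_table()];
#'   `write_calibration()` returns `path` invisibly.
#' @export
read_calibration <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$calibration)) {
    stop("calibration file ", path, " has no 'calibration' key")
  }
  entries <- lapply(doc$calibration, function(b) {
    calibration_entry(b$kvp, b$ctn_mar, b$ctn_cor, b$rho_cor,
                      ctn_mar_sd = if (is.null(b$ctn_mar_sd)) 0 else b$ctn_mar_sd,
                      ctn_cor_sd = if (is.null(b$ctn_cor_sd)) 0 else b$ctn_cor_sd)
  })
  calibration_table(entries)
}

#' @rdname read_calibration
#' @param calib a [calibration_table()] to serialize.
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "calibration_table"))
  blocks <- lapply(seq_len(nrow(calib)), function(i) {
    list(kvp = calib$kvp[i],
         ctn_mar = calib$ctn_mar[i], ctn_mar_sd = calib$ctn_mar_sd[i],
         ctn_cor = calib$ctn_cor[i], ctn_cor_sd = calib$ctn_cor_sd[i],
         rho_cor = calib$rho_cor[i])
  })
  yaml::write_yaml(list(calibration = blocks), path)
  invisible(path)
}
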