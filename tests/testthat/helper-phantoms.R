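# Shared fixtures: default calibration, forward model at 120 kVp, and
# memoised phantom renders so expensive scenes are rasterized once per run.

calib_default <- default_calibration()
entry120 <- calibration_for(calib_default, 120)
model120 <- forward_model(calib = calib_default, kvp = 120)

vial_densities <- c(0.135, 0.202, 0.267, 0.300, 0.344, 0.401, 0.467)

# centre of vial i in 0-based pixel coordinates (0.5 mm spacing)
vial_center_px <- function(i) c(20 / 0.5 - 0.5, (20 + (i - 1) * 25) / 0.5 - 0.5)

# printed seven-vial validation vectors (nominal and recovered)
vials_real <- c(0.135, 0.202, 0.267, 0.300, 0.344, 0.401, 0.467)
vials_calc <- c(0.143, 0.215, 0.276, 0.306, 0.363, 0.407, 0.468)

.render_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.render_cache[[key]])) .render_cache[[key]] <- force(expr)
  .render_cache[[key]]
}

seven_vials_image <- function(noise_sd = NULL, seed = 20L) {
  key <- paste0("vials_", ifelse(is.null(noise_sd), "def", noise_sd), "_", seed)
  cached(key, {
    spec <- builtin_phantom("seven_vials", noise_sd = noise_sd, seed = seed)
    render_phantom(spec, model120)
  })
}

forearm_image <- function(noise_sd = NULL, seed = 20L) {
  key <- paste0("forearm_", ifelse(is.null(noise_sd), "def", noise_sd), "_", seed)
  cached(key, {
    spec <- builtin_phantom("forearm_qrm", noise_sd = noise_sd, seed = seed)
    render_phantom(spec, model120)
  })
}

# recover per-vial vBMD through interior circular ROIs (diameter in mm)
recover_vials <- function(img, roi_diameter = 16) {
  vapply(seq_along(vial_densities), function(i) {
    roi <- roi_spec("circle", center = vial_center_px(i),
                    extent_mm = roi_diameter)
    ctn_to_bvf_vbmd(roi_stats(img, roi)$mean, entry120)$vbmd
  }, numeric(1))
}

# forearm section centres, 0-based pixels (0.25 mm spacing)
forearm_section_px <- function(i) c(c(13, 27, 41, 55)[i] / 0.25 - 0.5, 20 / 0.25 - 0.5)
forearm_densities <- c(0.194, 0.103, 0.054, 0)

recover_forearm <- function(img, extent_mm = 7) {
  vapply(1:4, function(i) {
    roi <- roi_spec("rectangle", center = forearm_section_px(i),
                    extent_mm = extent_mm)
    ctn_to_bvf_vbmd(roi_stats(img, roi)$mean, entry120)$vbmd
  }, numeric(1))
}
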