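test_that("bone segmentation fills enclosed marrow and voids into the mask", {
  spec <- builtin_phantom("toy_femur", noise_sd = 0, interior_vbmd = 0.17,
                          void = TRUE)
  img <- render_phantom(spec, model120)
  mask <- segment_bone(img)          # default 250 HU
  # the void centre is far below threshold yet inside the filled contour
  expect_lt(img$voxels[60, 60], 250)
  expect_true(mask[60, 60])
  # the trabecular interior (~242 HU) is likewise included by filling
  expect_true(mask[60, 75])
  # soft tissue outside the shell stays out
  expect_false(mask[5, 5])
  # without filling, only the supra-threshold shell remains
  shell_only <- segment_bone(img, fill = FALSE)
  expect_false(shell_only[60, 60])
  expect_lt(sum(shell_only), sum(mask))
})

test_that("a slice with no bone raises a distinct error", {
  img <- ct_image(matrix(40, 30, 30), pixel_spacing = 1)
  expect_error(segment_bone(img), "no pixels above the 250")
})

test_that("segmented disk area matches the geometric oracle within 2%", {
  spec <- phantom_spec(dim_px = c(100, 100), pixel_spacing = 0.5,
                       shapes = list(shape_disk(c(25, 25), 30, vbmd = 0.533)),
                       background_hu = 0, noise_sd = 0, supersample = 8L)
  img <- render_phantom(spec, model120)
  mask <- segment_bone(img)
  area <- sum(mask) * prod(img$pixel_spacing)
  expect_equal(area, pi * 15^2, tolerance = 0.02)
})

test_that("slice selection takes the maximum-area slice and its neighbours", {
  mk_vol <- function(sizes) {
    vox <- array(0, c(20, 20, length(sizes)))
    for (k in seq_along(sizes)) {
      s <- sizes[k]
      vox[10 + seq_len(s) - ceiling(s / 2), 10 + seq_len(s) - ceiling(s / 2), k] <- 300
    }
    ct_image(vox, pixel_spacing = 1, slice_thickness = 3, kvp = 120)
  }
  roi_all <- roi_spec("rectangle", center = c(9.5, 9.5), extent_mm = 20)

  sel <- select_voi_slices(mk_vol(c(2, 3, 5, 3, 2)), roi_all)
  expect_equal(sel$slices, 2:4)
  expect_equal(sel$best, 3L)
  expect_false(sel$tie); expect_false(sel$boundary)

  tie <- select_voi_slices(mk_vol(c(3, 5, 5, 3, 3)), roi_all)
  expect_equal(tie$best, 2L)          # tie broken toward the lower index
  expect_equal(tie$slices, 1:3)
  expect_true(tie$tie)

  bnd <- select_voi_slices(mk_vol(c(5, 3, 2)), roi_all)
  expect_equal(bnd$slices, 1:2)       # only one neighbour available
  expect_true(bnd$boundary)
})

test_that("the toy femur volume peaks at the requested slice", {
  vol <- toy_femur_volume(n_slices = 7, peak_slice = 4, noise_sd = 0, seed = 5)
  roi_wide <- roi_spec("circle", center = c(59.5, 59.5), extent_mm = 40)
  sel <- select_voi_slices(vol, roi_wide)
  expect_equal(sel$best, 4L)
  expect_equal(sel$slices, 3:5)
  expect_false(sel$boundary)
})

test_that("noise-free uniform interiors are recovered exactly", {
  vol <- toy_femur_volume(n_slices = 5, peak_slice = 3, interior_vbmd = 0.15,
                          void = FALSE, noise_sd = 0, seed = 2)
  roi <- roi_spec("circle", center = c(59.5, 59.5), extent_mm = 22)
  res <- femoral_neck_vbmd(vol, roi, calib_default)
  expect_equal(res$vbmd, 0.15, tolerance = 1e-9)
  # invariant: reported vBMD is the conversion of the VOI mean CTN
  expect_equal(res$vbmd, ctn_to_bvf_vbmd(res$mean_ctn, entry120)$vbmd)
})

test_that("interior vBMD is recovered within 0.005 g/cm^3 under 16.4 HU noise", {
  roi <- roi_spec("circle", center = c(59.5, 59.5), extent_mm = 22)
  for (nominal in c(0.10, 0.15, 0.20)) {
    vol <- toy_femur_volume(n_slices = 5, peak_slice = 3,
                            interior_vbmd = nominal, void = FALSE,
                            noise_sd = 16.4, seed = 40 + round(nominal * 100))
    res <- femoral_neck_vbmd(vol, roi, calib_default)
    expect_gte(res$n_voxels, 3000L)
    expect_lt(abs(res$vbmd - nominal), 0.005)
  }
})

test_that("VOI averaging commutes with conversion (affine map)", {
  vol <- toy_femur_volume(n_slices = 5, peak_slice = 3, interior_vbmd = 0.17,
                          noise_sd = 16.4, seed = 9)
  roi <- roi_spec("circle", center = c(59.5, 59.5), extent_mm = 22)
  res <- femoral_neck_vbmd(vol, roi, calib_default)
  voi_vals <- unlist(lapply(seq_along(res$selected_slices), function(i) {
    vol$voxels[, , res$selected_slices[i]][res$voi_mask[, , i]]
  }))
  dm <- ctn_to_bvf_vbmd(voi_vals, entry120)
  expect_equal(mean(dm$vbmd), res$vbmd, tolerance = 1e-12)
})

test_that("a low-density neck is classified osteoporotic", {
  vol <- toy_femur_volume(n_slices = 5, peak_slice = 3, interior_vbmd = 0.06,
                          void = FALSE, noise_sd = 16.4, seed = 13)
  roi <- roi_spec("circle", center = c(59.5, 59.5), extent_mm = 22)
  res <- femoral_neck_vbmd(vol, roi, calib_default)
  expect_lt(res$vbmd * 1000, 80)
  expect_equal(as.character(res$diagnostic$label), "osteoporosis")
})
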