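test_that("forward_ctn reproduces the calibration references", {
  expect_equal(forward_ctn(1, model120), 739.5)
  expect_equal(forward_ctn(0, model120), 8.7)
  # a 0.800 g/cm^3 wall against the 0.533 reference: BVF > 1, and the
  # inversion recovers the nominal density
  ctn_wall <- forward_ctn(0.800 / 0.533, model120)
  expect_equal(ctn_to_bvf_vbmd(ctn_wall, entry120)$vbmd, 0.800,
               tolerance = 1e-9)
  # water-equivalent mixture in attenuation mode is 0 HU for any bvf
  m <- forward_model(mu_a = 0.2, mu_b = 0.2, mu_water = 0.2, rho_cor = 0.533)
  expect_equal(forward_ctn(c(0, 0.3, 1), m), c(0, 0, 0))
  expect_error(forward_model(mu_a = 0.3, mu_b = 0.19, mu_water = 0,
                             rho_cor = 0.533), "mu_water")
})

test_that("attenuation and calibrated modes agree when mu values match", {
  mu_w <- 0.19
  m_att <- forward_model(mu_a = mu_w * (1 + 739.5 / 1000),
                         mu_b = mu_w * (1 + 8.7 / 1000),
                         mu_water = mu_w, rho_cor = 0.533)
  set.seed(11)
  bvf <- runif(50, 0, 1.6)
  expect_equal(forward_ctn(bvf, m_att), forward_ctn(bvf, model120),
               tolerance = 1e-9)
})

test_that("noise-free renders are exact in shape interiors and deterministic", {
  spec <- phantom_spec(dim_px = c(60, 60), pixel_spacing = 1,
                       shapes = list(shape_disk(c(30, 30), 40, vbmd = 0.533)),
                       background_hu = 0, noise_sd = 0)
  img <- render_phantom(spec, model120)
  # interior pixels (well away from the rim) carry the cortical reference HU
  expect_equal(img$voxels[30, 30], 739.5)
  expect_equal(img$voxels[25, 35], 739.5)
  # determinism with noise: same seed, identical images
  specn <- phantom_spec(dim_px = c(40, 40), pixel_spacing = 1,
                        shapes = list(shape_disk(c(20, 20), 20, vbmd = 0.3)),
                        noise_sd = 16.4, seed = 99L)
  i1 <- render_phantom(specn, model120)
  i2 <- render_phantom(specn, model120)
  expect_identical(i1$voxels, i2$voxels)
  # rendering does not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(render_phantom(specn, model120)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("shapes outside the canvas are rejected", {
  spec <- phantom_spec(dim_px = c(40, 40), pixel_spacing = 1,
                       shapes = list(shape_disk(c(38, 20), 20, vbmd = 0.2)))
  expect_error(render_phantom(spec, model120), "outside")
})

test_that("built-in scenes carry the nominal geometries and densities", {
  sv <- builtin_phantom("seven_vials")
  expect_length(sv$shapes, 7L)
  expect_equal(vapply(sv$shapes, `[[`, numeric(1), "vbmd"), vial_densities)
  expect_true(all(vapply(sv$shapes, `[[`, character(1), "type") == "disk"))

  fa <- builtin_phantom("forearm_qrm")
  walls <- Filter(function(s) !is.null(s$vbmd) && s$vbmd == 0.800, fa$shapes)
  expect_length(walls, 4L)
  for (w in walls) {
    inner <- Filter(function(s) !is.null(s$vbmd) && s$vbmd != 0.800 &&
                      identical(s$center, w$center), fa$shapes)[[1]]
    expect_equal((w$width - inner$width) / 2, 1.2)    # 1.2 mm wall
    expect_equal((w$height - inner$height) / 2, 1.2)
  }
  expect_setequal(vapply(Filter(function(s) !is.null(s$vbmd) && s$vbmd != 0.8,
                                fa$shapes), `[[`, numeric(1), "vbmd"),
                  forearm_densities)

  expect_error(builtin_phantom("spine"), "seven_vials, forearm_qrm, toy_femur")
})

test_that("noise-free render then inversion recovers nominal vBMD in interiors", {
  img <- seven_vials_image(noise_sd = 0)
  rec <- recover_vials(img, roi_diameter = 16)
  expect_equal(rec, vial_densities, tolerance = 1e-9)
})

test_that("per-vial ROI means sit within the sampling bound of the forward CTN", {
  img <- seven_vials_image()   # default sigma = 16.4 HU at 120 kVp
  for (i in seq_along(vial_densities)) {
    roi <- roi_spec("circle", center = vial_center_px(i), extent_mm = 16)
    s <- roi_stats(img, roi)
    expect_gte(s$n_pixels, 400L)
    bound <- 3 * 16.4 / sqrt(s$n_pixels)
    expect_lt(abs(s$mean - vbmd_to_ctn(vial_densities[i], entry120)), bound)
  }
})

test_that("recovered vBMD noise follows the delta-method prediction", {
  # uniform water bath, sigma = 16.4 HU, > 1e4 pixels
  spec <- phantom_spec(dim_px = c(120, 120), pixel_spacing = 1,
                       shapes = list(), background_hu = 8.7,
                       noise_sd = 16.4, seed = 17L)
  dm <- ctn_to_bvf_vbmd(render_phantom(spec, model120), entry120, kvp = 120)
  predicted <- 16.4 * 0.533 / (739.5 - 8.7)
  expect_equal(sd(dm$vbmd), predicted, tolerance = 0.1)
})

test_that("cupping depresses recovered vBMD at a dense shape's centre", {
  spec <- phantom_spec(dim_px = c(80, 80), pixel_spacing = 0.5,
                       shapes = list(shape_disk(c(20, 20), 30, vbmd = 0.533)),
                       background_hu = 0, noise_sd = 0,
                       cupping_amplitude = 50)
  dm <- ctn_to_bvf_vbmd(render_phantom(spec, model120), entry120, kvp = 120)
  center <- dm$vbmd[40, 40]
  edge <- dm$vbmd[40, 40 + 24]   # r = 12 mm of a 15 mm radius disk
  expect_lt(center, edge)
  expect_lt(center, 0.533)
})
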