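# Synthetic phantom simulator: forward model + geometry rasterizer.
# Generates the scenes used to validate the two-compartment inversion —
# a calibration vial array, a forearm-style insert phantom and a toy
# proximal femur — with partial-volume rendering, an optional
# beam-hardening cupping deficit, and additive Gaussian HU noise.

#' Forward model mapping bone volume fraction to CT number
#'
#' Two equivalent parameterizations:
#' * **calibrated** (default): affine in BVF,
#'   \eqn{CTN = BVF (CTN_{cor} - CTN_{mar}) + CTN_{mar}} — exactly the map
#'   that [ctn_to_bvf_vbmd()] inverts;
#' * **attenuation**: from spectrum-weighted linear attenuation
#'   coefficients, \eqn{CTN = (\bar\mu_{mix}/\tilde\mu_{H_2O} - 1) \cdot
#'   1000} with \eqn{\bar\mu_{mix} = v\,\tilde\mu_a + (1-v)\tilde\mu_b}.
#'
#' The modes coincide when the \eqn{\mu} values are chosen so the pure
#' materials reproduce `ctn_cor` and `ctn_mar`.
#'
#' @param calib a [calibration_entry()] or [calibration_table()] (calibrated
#'   mode).
#' @param kvp entry selector when `calib` is a table.
#' @param mu_a,mu_b,mu_water spectrum-weighted linear attenuation
#'   coefficients (1/cm) of the cortical-equivalent material, the marrow
#'   surrogate and water (attenuation mode; `mu_water > 0`).
#' @param rho_cor mineral-equivalent density (g/cm^3) used to convert a
#'   nominal vBMD into a BVF; defaults to the calibration entry's value.
#' @return An object of class `forward_model`.
#' @export
forward_model <- function(calib = NULL, kvp = NULL,
                          mu_a = NULL, mu_b = NULL, mu_water = NULL,
                          rho_cor = NULL) {
  if (!is.null(calib)) {
    entry <- calibration_for(calib, kvp)
    structure(list(mode = "calibrated", entry = entry,
                   rho_cor = if (is.null(rho_cor)) entry$rho_cor else rho_cor,
                   kvp = entry$kvp),
              class = "forward_model")
  } else {
    if (is.null(mu_a) || is.null(mu_b) || is.null(mu_water)) {
      stop("attenuation mode needs mu_a, mu_b and mu_water")
    }
    if (mu_water <= 0) stop("mu_water must be positive")
    if (is.null(rho_cor)) stop("attenuation mode needs rho_cor to map vBMD to BVF")
    structure(list(mode = "attenuation", mu_a = mu_a, mu_b = mu_b,
                   mu_water = mu_water, rho_cor = rho_cor,
                   kvp = if (is.null(kvp)) NA_integer_ else as.integer(kvp)),
              class = "forward_model")
  }
}

#' CT number of a voxel with a given bone volume fraction
#'
#' @param bvf bone volume fraction(s); values above 1 are allowed (they
#'   model material denser than the calibration phantom, e.g. a 0.800
#'   g/cm^3 cortical wall against a 0.533 g/cm^3 reference).
#' @param model a [forward_model()].
#' @return CT number(s), HU. Affine in `bvf` in both modes.
#' @export
forward_ctn <- function(bvf, model) {
  stopifnot(inherits(model, "forward_model"), is.numeric(bvf))
  if (any(bvf < 0)) stop("bvf must be non-negative")
  if (model$mode == "calibrated") {
    e <- model$entry
    bvf * (e$ctn_cor - e$ctn_mar) + e$ctn_mar
  } else {
    mu_mix <- bvf * model$mu_a + (1 - bvf) * model$mu_b
    (mu_mix / model$mu_water - 1) * 1000
  }
}

# ---- shape primitives (mm coordinates, (y, x) = (row, col) order) ------

#' Phantom shape primitives
#'
#' Shapes are placed on the canvas in millimetre coordinates, `(y, x)` with
#' the origin at the top-left image corner (matching `(row, col)` pixel
#' order). Each shape carries either a nominal `vbmd` (g/cm^3), converted
#' to HU through the forward model at render time, or an explicit `hu`.
#' Later shapes overwrite earlier ones (painter's order). `dense` marks a
#' shape as subject to the beam-hardening cupping deficit; by default any
#' shape with nominal vBMD >= 0.5 g/cm^3 is treated as dense.
#'
#' @param center_mm `(y, x)` centre, mm.
#' @param diameter_mm,inner_diameter_mm,outer_diameter_mm disk/annulus
#'   diameters, mm.
#' @param width_mm,height_mm rectangle extents, mm.
#' @param vbmd nominal vBMD, g/cm^3 (mutually exclusive with `hu`).
#' @param hu explicit CT number, HU.
#' @param dense logical; `NULL` means "vbmd >= 0.5".
#' @return A `phantom_shape` list.
#' @name phantom_shapes
NULL

new_shape <- function(type, center_mm, vbmd, hu, dense, ...) {
  if (is.null(vbmd) && is.null(hu)) stop("shape needs vbmd or hu")
  if (!is.null(vbmd) && !is.null(hu)) stop("give vbmd or hu, not both")
  if (is.null(dense)) dense <- !is.null(vbmd) && vbmd >= 0.5
  structure(list(type = type, center = as.numeric(center_mm),
                 vbmd = vbmd, hu = hu, dense = dense, ...),
            class = "phantom_shape")
}

#' @rdname phantom_shapes
#' @export
shape_disk <- function(center_mm, diameter_mm, vbmd = NULL, hu = NULL,
                       dense = NULL) {
  stopifnot(diameter_mm > 0)
  new_shape("disk", center_mm, vbmd, hu, dense, diameter = diameter_mm)
}

#' @rdname phantom_shapes
#' @export
shape_annulus <- function(center_mm, inner_diameter_mm, outer_diameter_mm,
                          vbmd = NULL, hu = NULL, dense = NULL) {
  stopifnot(outer_diameter_mm > inner_diameter_mm, inner_diameter_mm >= 0)
  new_shape("annulus", center_mm, vbmd, hu, dense,
            inner = inner_diameter_mm, outer = outer_diameter_mm)
}

#' @rdname phantom_shapes
#' @export
shape_rect <- function(center_mm, width_mm, height_mm, vbmd = NULL,
                       hu = NULL, dense = NULL) {
  stopifnot(width_mm > 0, height_mm > 0)
  new_shape("rect", center_mm, vbmd, hu, dense,
            width = width_mm, height = height_mm)
}

shape_mask <- function(shape, Y, X) {
  cy <- shape$center[1]; cx <- shape$center[2]
  switch(shape$type,
    disk = (Y - cy)^2 + (X - cx)^2 <= (shape$diameter / 2)^2,
    annulus = {
      r2 <- (Y - cy)^2 + (X - cx)^2
      r2 <= (shape$outer / 2)^2 & r2 >= (shape$inner / 2)^2
    },
    rect = abs(Y - cy) <= shape$height / 2 & abs(X - cx) <= shape$width / 2,
    stop("unknown shape type ", shape$type))
}

shape_bbox <- function(shape) {
  cy <- shape$center[1]; cx <- shape$center[2]
  half <- switch(shape$type,
    disk = c(shape$diameter, shape$diameter) / 2,
    annulus = c(shape$outer, shape$outer) / 2,
    rect = c(shape$height, shape$width) / 2)
  list(y = c(cy - half[1], cy + half[1]), x = c(cx - half[2], cx + half[2]))
}

shape_radius <- function(shape) {
  switch(shape$type,
    disk = shape$diameter / 2,
    annulus = shape$outer / 2,
    rect = sqrt(shape$width^2 + shape$height^2) / 2)
}

#' Declarative phantom specification
#'
#' @param dim_px canvas dimensions `(rows, cols)`, pixels.
#' @param pixel_spacing `(row, col)` pixel spacing, mm.
#' @param shapes list of [phantom_shapes] in painter's order.
#' @param background_hu canvas background CT number, HU.
#' @param noise_sd standard deviation of the additive i.i.d. Gaussian HU
#'   noise (>= 0).
#' @param cupping_amplitude beam-hardening cupping amplitude, HU (>= 0).
#'   Inside each dense shape the rendered CT number is multiplied by
#'   `1 - a (1 - r/R)` with `a = cupping_amplitude / 1000`, `r` the distance
#'   from the shape centre and `R` its outer radius: a radially increasing
#'   deficit toward the centre, the qualitative signature of beam
#'   hardening.
#' @param supersample integer >= 1; shapes are rasterized on a grid this
#'   many times finer and box-averaged down, producing the partial-volume
#'   mixing seen at real interfaces.
#' @param seed RNG seed for the noise draw.
#' @param name optional label recorded in the provenance.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim_px, pixel_spacing, shapes = list(),
                         background_hu = 0, noise_sd = 0,
                         cupping_amplitude = 0, supersample = 8L,
                         seed = 1L, name = NULL) {
  stopifnot(length(dim_px) == 2L, all(dim_px >= 1L),
            length(pixel_spacing) %in% c(1L, 2L), all(pixel_spacing > 0),
            noise_sd >= 0, cupping_amplitude >= 0, supersample >= 1L)
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  structure(list(dim_px = as.integer(dim_px),
                 pixel_spacing = as.numeric(pixel_spacing),
                 shapes = shapes, background_hu = background_hu,
                 noise_sd = noise_sd, cupping_amplitude = cupping_amplitude,
                 supersample = as.integer(supersample),
                 seed = as.integer(seed), name = name),
            class = "phantom_spec")
}

# box-average an (nr*s) x (nc*s) matrix down to nr x nc
box_downsample <- function(M, s) {
  if (s == 1L) return(M)
  nr <- nrow(M) %/% s; nc <- ncol(M) %/% s
  A <- matrix(colMeans(matrix(M, nrow = s)), nrow = nr)        # nr x (nc*s)
  t(matrix(colMeans(matrix(t(A), nrow = s)), nrow = nc))       # nr x nc
}

with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Render a phantom specification to a CT image
#'
#' Rasterizes the shapes at `supersample`-fold resolution, converts nominal
#' vBMD to HU through the forward model, box-averages to the canvas grid
#' (partial volume), applies the cupping deficit inside dense shapes, and
#' finally adds i.i.d. Gaussian HU noise drawn under the spec's seed. The
#' same spec and seed always render to the identical image.
#'
#' @param spec a [phantom_spec()].
#' @param model a [forward_model()].
#' @return A [ct_image()] whose provenance records the spec name and seed.
#' @export
render_phantom <- function(spec, model) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(model, "forward_model"))
  nr <- spec$dim_px[1]; nc <- spec$dim_px[2]
  sp <- spec$pixel_spacing; s <- spec$supersample
  ext <- c(nr * sp[1], nc * sp[2])
  for (sh in spec$shapes) {
    bb <- shape_bbox(sh)
    if (bb$y[1] < 0 || bb$x[1] < 0 || bb$y[2] > ext[1] || bb$x[2] > ext[2]) {
      stop(sprintf("shape '%s' at (%.1f, %.1f) mm extends outside the %.1f x %.1f mm canvas",
                   sh$type, sh$center[1], sh$center[2], ext[1], ext[2]))
    }
  }
  ys <- (seq_len(nr * s) - 0.5) * sp[1] / s
  xs <- (seq_len(nc * s) - 0.5) * sp[2] / s
  Ys <- matrix(ys, nr * s, nc * s)
  Xs <- matrix(xs, nr * s, nc * s, byrow = TRUE)
  img <- matrix(spec$background_hu, nr * s, nc * s)
  for (sh in spec$shapes) {
    hu <- if (!is.null(sh$hu)) sh$hu else
      forward_ctn(sh$vbmd / model$rho_cor, model)
    img[shape_mask(sh, Ys, Xs)] <- hu
  }
  img <- box_downsample(img, s)
  if (spec$cupping_amplitude > 0) {
    a <- spec$cupping_amplitude / 1000
    Y <- matrix((seq_len(nr) - 0.5) * sp[1], nr, nc)
    X <- matrix((seq_len(nc) - 0.5) * sp[2], nr, nc, byrow = TRUE)
    for (sh in spec$shapes) {
      if (!isTRUE(sh$dense)) next
      m <- shape_mask(sh, Y, X)
      r <- sqrt((Y - sh$center[1])^2 + (X - sh$center[2])^2)
      R <- shape_radius(sh)
      fac <- 1 - a * pmax(0, 1 - r / R)
      img[m] <- img[m] * fac[m]
    }
  }
  if (spec$noise_sd > 0) {
    img <- img + with_seed(spec$seed,
                           matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc))
  }
  ct_image(img, pixel_spacing = sp, slice_thickness = 1,
           kvp = model$kvp,
           provenance = list(generator = "qctbone::render_phantom",
                             spec = spec$name, seed = spec$seed,
                             noise_sd = spec$noise_sd,
                             supersample = spec$supersample))
}

#' Built-in phantom scenes
#'
#' Fully parameterized specifications of the three validation scenes:
#'
#' * `seven_vials` — an array of seven 20 mm K2HPO4 vials with nominal
#'   mineral densities 0.135, 0.202, 0.267, 0.300, 0.344, 0.401 and
#'   0.467 g/cm^3 in a water bath, left to right.
#' * `forearm_qrm` — a forearm-style calibration phantom: a 6 cm body with
#'   four stacked sections of 0.194, 0.103, 0.054 and 0 g/cm^3
#'   hydroxyapatite-equivalent density on the left, each enclosed in a
#'   1.2 mm wall of 0.800 g/cm^3, and two water inserts (4.5 cm and 1.5 cm
#'   tall) on the right.
#' * `toy_femur` — a schematic proximal-femur cross-section: a dense
#'   cortical shell, a trabecular interior (default 0.17 g/cm^3) and an
#'   optional central nonosseous void.
#'
#' The default noise level is the cortical-phantom ROI standard deviation
#' of the calibration entry at the requested kVp (16.4 HU at 120 kVp).
#' Vial diameter (20 mm) and section interior sizes are package choices;
#' see the package vignette for the rationale.
#'
#' @param name one of `"seven_vials"`, `"forearm_qrm"`, `"toy_femur"`.
#' @param kvp tube voltage; selects the calibration entry.
#' @param calib calibration table, default [default_calibration()].
#' @param noise_sd Gaussian HU noise SD; `NULL` = the entry's `ctn_cor_sd`.
#' @param seed RNG seed stored in the spec.
#' @param interior_vbmd (`toy_femur`) trabecular interior density, g/cm^3.
#' @param void (`toy_femur`) include the central nonosseous void?
#' @param scale (`toy_femur`) isotropic scale factor for the bone cross
#'   section (used to vary the neck area across slices).
#' @return A [phantom_spec()].
#' @export
builtin_phantom <- function(name = c("seven_vials", "forearm_qrm", "toy_femur"),
                            kvp = 120, calib = default_calibration(),
                            noise_sd = NULL, seed = 1L,
                            interior_vbmd = 0.17, void = TRUE, scale = 1) {
  name <- tryCatch(match.arg(name),
                   error = function(e) stop(
                     "unknown phantom '", name[1],
                     "'; valid names: seven_vials, forearm_qrm, toy_femur"))
  entry <- calibration_for(calib, kvp)
  if (is.null(noise_sd)) noise_sd <- entry$ctn_cor_sd
  if (name == "seven_vials") {
    dens <- c(0.135, 0.202, 0.267, 0.300, 0.344, 0.401, 0.467)
    shapes <- lapply(seq_along(dens), function(i) {
      shape_disk(center_mm = c(20, 20 + (i - 1) * 25), diameter_mm = 20,
                 vbmd = dens[i])
    })
    phantom_spec(dim_px = c(80, 380), pixel_spacing = 0.5, shapes = shapes,
                 background_hu = 0, noise_sd = noise_sd, seed = seed,
                 name = "seven_vials")
  } else if (name == "forearm_qrm") {
    secs <- c(0.194, 0.103, 0.054, 0)
    sec_y <- c(13, 27, 41, 55)
    shapes <- list(shape_rect(c(35, 35), width_mm = 60, height_mm = 60, hu = 40))
    for (i in seq_along(secs)) {
      shapes <- c(shapes, list(
        shape_rect(c(sec_y[i], 20), width_mm = 22.4, height_mm = 12.4,
                   vbmd = 0.800),
        shape_rect(c(sec_y[i], 20), width_mm = 20, height_mm = 10,
                   vbmd = secs[i])))
    }
    shapes <- c(shapes, list(
      shape_rect(c(27.5, 50), width_mm = 12, height_mm = 45, hu = 0),
      shape_rect(c(57.5, 50), width_mm = 12, height_mm = 15, hu = 0)))
    phantom_spec(dim_px = c(280, 280), pixel_spacing = 0.25, shapes = shapes,
                 background_hu = -1000, noise_sd = noise_sd, seed = seed,
                 name = "forearm_qrm")
  } else {
    shell_outer <- 36 * scale; shell_inner <- 30 * scale
    shapes <- list(
      shape_disk(c(30, 30), diameter_mm = 56, hu = 40),
      shape_annulus(c(30, 30), inner_diameter_mm = shell_inner,
                    outer_diameter_mm = shell_outer, vbmd = 0.800),
      shape_disk(c(30, 30), diameter_mm = shell_inner, vbmd = interior_vbmd))
    if (void) {
      shapes <- c(shapes, list(
        shape_disk(c(30, 30), diameter_mm = 8 * scale, vbmd = 0)))
    }
    phantom_spec(dim_px = c(120, 120), pixel_spacing = 0.5, shapes = shapes,
                 background_hu = -1000, noise_sd = noise_sd, seed = seed,
                 name = "toy_femur")
  }
}

#' Synthetic proximal-femur volume
#'
#' Stacks rendered toy-femur slices into a 3D volume whose bone
#' cross-section grows to a maximum at `peak_slice` and shrinks again —
#' the geometry the maximum-neck-area slice selection expects. Each slice
#' gets an independent noise draw (seed offset by the slice index).
#'
#' @param n_slices number of slices (>= 3).
#' @param peak_slice 1-based index of the largest cross-section.
#' @param interior_vbmd trabecular interior density, g/cm^3.
#' @param void include the central nonosseous void?
#' @inheritParams builtin_phantom
#' @param slice_thickness mm.
#' @return A 3D [ct_image()] (coronal orientation label).
#' @export
toy_femur_volume <- function(n_slices = 9, peak_slice = 5,
                             interior_vbmd = 0.17, void = TRUE,
                             kvp = 120, calib = default_calibration(),
                             noise_sd = NULL, seed = 1L,
                             slice_thickness = 3) {
  stopifnot(n_slices >= 3, peak_slice >= 1, peak_slice <= n_slices)
  model <- forward_model(calib = calib, kvp = kvp)
  slices <- vector("list", n_slices)
  for (k in seq_len(n_slices)) {
    sc <- 1 - 0.06 * abs(k - peak_slice)
    if (sc < 0.3) sc <- 0.3
    spec <- builtin_phantom("toy_femur", kvp = kvp, calib = calib,
                            noise_sd = noise_sd, seed = seed + k,
                            interior_vbmd = interior_vbmd, void = void,
                            scale = sc)
    spec$supersample <- 4L
    slices[[k]] <- render_phantom(spec, model)$voxels
  }
  vox <- array(unlist(slices), dim = c(dim(slices[[1]]), n_slices))
  ct_image(vox, pixel_spacing = c(0.5, 0.5), slice_thickness = slice_thickness,
           kvp = kvp, orientation = "coronal",
           provenance = list(generator = "qctbone::toy_femur_volume",
                             seed = seed, peak_slice = peak_slice,
                             interior_vbmd = interior_vbmd, void = void))
}
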