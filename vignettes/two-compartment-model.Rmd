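---
title: "The two-compartment model: from CT numbers to volumetric bone mineral density"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The two-compartment model: from CT numbers to volumetric bone mineral density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qctbone)
```

## The model

A CT voxel containing a mixture of two materials has a CT number that is
affine in the component volume fractions: the mixture's linear attenuation
coefficient is the volume-weighted sum of the component coefficients, and
the Hounsfield scale is itself an affine function of attenuation,
$CTN = 1000\,(\mu/\mu_{H_2O} - 1)$. Writing $v_a$ for the volume fraction
of material $a$,

$$v_a = \frac{CTN_{mix} - CTN_b}{CTN_a - CTN_b},$$

where the $/1000 + 1$ rescalings of the raw Hounsfield definition cancel
exactly (`volume_fraction()` returns this simplified ratio; a property
test checks agreement with the literal rescaled arithmetic to $10^{-12}$).

The two-compartment model (TCM) applies this with material $a$ a
cortical-bone-equivalent K$_2$HPO$_4$ solution and material $b$ a
bone-marrow surrogate (water). The bone volume fraction and volumetric
bone mineral density of a voxel are then

$$BVF = \frac{CTN_{mix} - CTN_{mar}}{CTN_{cor} - CTN_{mar}}, \qquad
  vBMD = BVF \cdot \rho_{cor},$$

with $CTN_{mar}$, $CTN_{cor}$ measured once per tube voltage from a water
vial and the cortical-equivalent phantom, and $\rho_{cor}$ the phantom's
mineral-equivalent density. `ctn_to_bvf_vbmd()` is this inversion,
element-wise over arrays.

Assumptions worth keeping in view:

* **Two compartments only.** Yellow/red marrow composition differences,
  soft-tissue inclusions and anything not on the water–cortical axis are
  projected onto it.
* **$\rho_{cor}$ is a mineral-equivalent density** — the K$_2$HPO$_4$ mass
  per solution volume of the calibration phantom (0.533 g/cm³ for the
  built-in calibration), not a physical mass density. Under this reading
  the mixture-density terms cancel and the inversion needs no voxel mass
  density. This is the only reading under which the cortical reference
  converts to its nominal 0.533 g/cm³.
* **Linearity of the scanner.** Beam hardening violates it for dense
  objects; the simulator can emulate the resulting cupping (below).

### Values outside [0, 1]

Nothing prevents a voxel denser than the calibration phantom: a
0.800 g/cm³ cortical wall against a 0.533 g/cm³ reference has
$BVF \approx 1.5$. The inversion therefore returns **raw** values by
default and treats clamping as an explicit option (`clamp = TRUE`), with
`clamped_mask` recording exactly which voxels fell outside $[0, 1]$.
Reported wall recoveries near 0.79 g/cm³ in the validation literature are
only possible without clamping, so raw output is the faithful default;
the mask makes the violated model assumption visible rather than silent.

### Diagnostic thresholds

`classify_acr()` applies the American College of Radiology quantitative-CT
cut-offs: osteoporosis strictly below 80 mg/cm³, osteopenia in the closed
interval [80, 120] mg/cm³, normal above. "Between 80 and 120" is read as a
closed interval so the boundary behaviour is unambiguous and testable;
units are g/cm³ internally, converted by an exact ×1000 at the
classification boundary only.

## Calibration

`roi_stats()` computes the ROI mean and **sample** standard deviation
(n − 1 denominator; the convention for ROI statistics) over pixels whose
centres lie inside the region. Rectangle edges are half-open (left/top
edge in, right/bottom out) so adjacent ROIs tile without double counting —
a deterministic, resolution-independent membership rule. The default ROI
extent mirrors the 30 mm × 30 mm cortical-phantom ROI; the water-vial ROI
is not separately dimensioned anywhere authoritative, so it uses the same
default.

`build_calibration()` rejects inverted scans (cortical mean ≤ water mean)
rather than producing a table that would later fail the
`ctn_cor > ctn_mar` invariant. The built-in table
(`default_calibration()`) carries the measured references: water
−11.1 ± 30.3 / 2.1 ± 23.7 / 8.7 ± 13.8 HU and cortical phantom
982.2 ± 41.4 / 830.0 ± 27.2 / 739.5 ± 16.4 HU at 80/100/120 kVp,
ρ_cor = 0.533 g/cm³. Tables serialize to a YAML config with one block per
kVp (`write_calibration()` / `read_calibration()`).

## The synthetic phantom simulator

The simulator exists so that the full validation chain — render a scene
with known ground truth, convert it, measure the recovery error — runs
without clinical data. `render_phantom()` proceeds in four steps:

1. **Rasterization at supersampled resolution.** Shapes (disks, annuli,
   rectangles, painter's order) are painted on a grid `supersample` times
   finer than the canvas (default 8) and box-averaged down. Boundary
   pixels therefore contain genuine partial-volume mixtures, which is why
   recovery tests use interior-eroded ROIs, exactly as one would on a real
   scan.
2. **Forward model.** Nominal vBMD is converted to HU through
   `forward_model()`. The default *calibrated* mode is affine in BVF —
   precisely the map the inversion undoes, keeping simulator and inversion
   closed under the same algebra. An *attenuation* mode accepts
   spectrum-weighted μ values for users who have them; the two modes agree
   when the μ values reproduce the calibration references (tested).
   Published spectrum-weighted μ values were not available, so calibrated
   mode is the default.
3. **Cupping (optional).** Beam hardening depresses CT numbers toward the
   centre of dense objects. The simulator uses the simplest monotone
   model: inside each dense shape the HU is multiplied by
   $1 - a\,(1 - r/R)$ with $a = \mathrm{cupping\_amplitude}/1000$. Only
   the direction of the effect is scientifically asserted (centre
   recovered lower than edge); no quantitative cupping claim is made.
4. **Noise.** i.i.d. Gaussian HU noise under the phantom
   specification's seed, drawn
   without disturbing the caller's RNG stream. Real reconstruction noise
   is spatially correlated; only per-ROI standard deviations are being
   emulated, so i.i.d. noise is sufficient for the statistics computed
   here and nothing finer-grained should be read into it. The default
   noise SD is the cortical-phantom ROI SD at the selected kVp
   (16.4 HU at 120 kVp) — the more conservative of the two measured SDs.

Images stay floating-point HU; integer quantization is a storage concern,
not a model concern, and coupling the math tests to it would only blur
tolerances.

### Built-in scenes and chosen sizes

* `seven_vials`: seven 20 mm vials (0.135–0.467 g/cm³) in a water bath on
  a 40 × 190 mm canvas at 0.5 mm pixels. Vial diameter and ROI sizes are
  package choices (the originals are not recorded): 20 mm vials admit
  16 mm interior ROIs of ~800 pixels, comfortably above the ≥400-pixel
  ROI size the recovery analyses assume, while keeping renders under a
  second.
* `forearm_qrm`: the densities (0.194/0.103/0.054/0 g/cm³), the 1.2 mm
  0.800 g/cm³ walls and the 4.5/1.5 cm water-insert heights are nominal;
  the slice layout is not fully specified anywhere, so the scene is a
  longitudinal slice with the four walled sections stacked on the left
  (20 × 10 mm interiors) and the two water columns on the right, at
  0.25 mm pixels so the 1.2 mm wall spans ~5 pixels.
* `toy_femur`: a schematic cross-section — dense shell (0.800 g/cm³),
  trabecular interior (default 0.17 g/cm³), optional central void — *not*
  anatomically realistic. `toy_femur_volume()` stacks slices whose bone
  cross-section peaks at a chosen slice, which is all the slice-selection
  logic needs.

What passing these tests shows: the inversion, calibration plumbing, ROI
statistics and VOI protocol are correct, and recovery errors under the
measured noise levels are far inside the reported error envelopes. What
they do not show: performance on real scanners (correlated noise, scatter,
actual beam-hardening spectra, patient positioning) or on real femoral
anatomy.

## The femoral-neck protocol

`segment_bone()` thresholds at 250 HU, keeps the largest connected
component and fills holes (EBImage morphology). Filling is a scientific
choice, not cosmetic: trabecular bone at, say, 0.17 g/cm³ sits *below*
250 HU at 120 kVp, so an unfilled mask would contain only the cortical
shell and the VOI mean would be biased far upward — values like
0.123 g/cm³ for a whole neck are only reachable when marrow and
nonosseous voids count. A `bone_only` flag switches to
supra-threshold-only averaging for sensitivity analysis.

`select_voi_slices()` measures the filled-bone area inside the
operator-supplied neck ROI on every slice and takes the argmax plus its
two neighbours. Ties break toward the lower index and are flagged; an
argmax at the volume boundary returns the two available neighbours and is
flagged. One degenerate case is worth knowing: if the neck ROI lies
strictly inside the bone on every slice, all areas tie exactly and the
rule selects the first slices — flagged, and harmless when the interior
is homogeneous, but an ROI wider than the bone gives the intended
strict-peak behaviour.

The VOI mean CT number is converted once; because the inversion is
affine, this equals averaging a converted map over the VOI (asserted
numerically). The neck ROI is an explicit input throughout — observers
draw it; there is no automatic neck detection.

## Statistics

* `pearson_fit()` wraps base R's `lm`/`cor.test` (slope, intercept, r,
  two-sided p on n − 2 df).
* `age_trend()` reports the slope as a loss rate,
  $-\text{slope}/\text{baseline} \times 100$ %/year. The baseline is the
  group mean vBMD by default; nothing in the source material defines the
  baseline, and the group mean reproduces the magnitude of the published
  rates from the published group statistics without inventing a reference
  age. `baseline = "min_age"` (fitted value at the youngest age) is the
  documented alternative.
* `icc_consistency()` implements ICC(3,1), consistency: two-way mixed
  ANOVA mean squares computed in-package,
  $ICC = (BMS - EMS)/(BMS + (k-1)EMS)$, with the 95% CI from the
  Shrout–Fleiss F bounds. Tests cross-check the point estimate against an
  independent `aov()` oracle to $10^{-10}$ and assert the consistency
  property (invariance to per-rater offsets and to global rescaling).
  Degenerate input (zero residual mean square) returns ICC 1 with a
  degenerate CI; zero between-subject variance is an error, not a number.
* `difference_summary()` is the per-item signed difference plus
  mean/max absolute difference used for vial validation.

### The synthetic cohort

`simulate_cohort()` emulates a retrospective clinical cohort: 17 males
(30–69 y) and 11 females (34–59 y), mean vBMD 0.166 g/cm³, mean aBMD
0.892 g/cm². The generating slopes come from loss rates of 0.898 %/year
(female) and 0.290 %/year (male) applied to the mean vBMD; residual SDs
(0.0138 / 0.024 g/cm³) are back-solved so the expected age correlations
are ≈ −0.615 and −0.220; the aBMD link is scaled for an expected
vBMD–aBMD correlation of 0.92 (marginal SDs 0.025 and 0.130). These are
*generator* parameters: at n = 28 any single realization scatters widely
around them, which is exactly why the clinical correlations are covered
by parameter-recovery tests rather than by point reproduction. The
recovery property (fitted slope within 2 SE of truth in ≥93/100 seeded
replicates) is run on 40-per-sex cohorts because ±2 SE carries only
~92% t-coverage at n = 11 — at that size the bound would fail in
expectation for a *correct* implementation.

## Numerical choices and degenerate inputs

* Coordinates are 0-based `(row, col)` pixels; profile positions in mm.
* Degenerate calibration (`ctn_cor ≤ ctn_mar`, or `ctn_a = ctn_b`) is an
  error everywhere, never an Inf/NaN propagated silently; a missing kVp
  entry names the available voltages.
* The portable image format writes doubles at 17 significant digits, so
  write→read round trips are exact.
* Problem sizes were chosen so the whole validation chain is fast: the
  vial scene renders in ~0.5 s, the forearm scene in ~3 s (supersample 8
  at 0.25 mm pixels), femur volumes in well under a second; the full test
  suite runs in seconds.

## Known limitations

* No DICOM reader/writer: images enter as in-memory arrays or through the
  portable text format.
* No projection/reconstruction physics: the cupping model is qualitative,
  and scatter, metal artifacts and correlated noise are absent.
* Single-energy only; no three-compartment (yellow/red marrow) extension.
* The toy femur is schematic; nothing here validates anatomical
  segmentation.
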