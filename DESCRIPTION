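Package: qctbone
Title: Volumetric Bone Mineral Density from CT Images via a Two-Compartment Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts computed tomography (CT) images, in Hounsfield units, to
    bone volume fraction (BVF) and volumetric bone mineral density (vBMD) maps
    using a linear two-compartment mixture model calibrated against a water
    (marrow-equivalent) vial and a cortical-bone-equivalent K2HPO4 phantom at
    each tube voltage. Includes per-kVp calibration from region-of-interest
    statistics, diagnostic classification against the ACR quantitative-CT
    thresholds, a femoral-neck volume-of-interest protocol (250 HU bone
    segmentation, maximum-neck-area slice selection), reliability and
    regression statistics (ICC(3,1) consistency, Pearson correlation, age
    trends), and a synthetic phantom simulator (calibration vials, a
    forearm-style insert phantom, and a toy proximal femur) that makes the
    whole validation chain reproducible without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    stats,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
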