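Package: ccperf
Title: Quantitative Dynamic Cardiac CT Perfusion Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline for quantitative myocardial blood flow (MBF)
    estimation from dynamic contrast-enhanced cardiac CT. Includes a digital
    short-axis left-ventricular phantom and synthetic-cohort generator with
    known ground truth; tracer-kinetic MBF estimation by a simplified
    Johnson-Wilson (one-compartment) model with superpixel (SLIC) aggregation
    for noise robustness; image-based automated beam-hardening correction;
    aorta detection, temporal registration and fallback heart segmentation;
    AHA 16-segment bullseye polar maps with territory statistics; and cohort
    tools for CAD-RADS grading, bootstrap ROC/Youden threshold derivation and
    classification of flow-limiting stenosis versus microvascular disease.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    pROC
Config/testthat/edition: 3
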