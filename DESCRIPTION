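Package: redoxwound
Title: Label-Free NADH/FAD Redox-Ratio Image Analysis for Wound Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the mitochondrial redox state of healing wounds from
    label-free NADH and FAD autofluorescence images. Implements
    cuvette-reference intensity calibration and flat-field correction,
    automated white-light wound segmentation, pixel- and voxel-wise NADH/FAD
    redox maps, Surface and Volumetric redox-ratio summaries, normalized
    wound-area closure curves, and the longitudinal statistics (two-factor
    repeated-measures ANOVA with Tukey post hoc contrasts and Pearson
    correlation) used to compare diabetic and control cohorts. Ships a
    synthetic-cohort generator with known ground truth that emulates in vivo
    fluorescence sessions and 3D cryo-imaging stacks, so the whole pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    ggplot2,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
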