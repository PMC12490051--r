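Package: histoquant
Title: Automated Histological Quantification for Whole-Section Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated quantification of histological sections:
    whole-section fluorescence mosaicking (tile stitching, bit-depth and
    gamma normalisation), marker-based watershed segmentation and counting
    of stained nuclei with data-driven size filtering, Cavalieri-principle
    estimation of tissue and lesion-cavity volumes from serial coronal
    sections, validation of automated counts against blinded manual counts,
    and an assumption-checked group-comparison procedure that routes between
    ANOVA with Tukey's HSD and Kruskal-Wallis with Dunn's post hoc test.
    Ships a synthetic-phantom generator (fluorescent nuclei fields and
    stained-section phantoms with analytically known areas) so the whole
    pipeline can be exercised against exact ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    car,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
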