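Package: petrousgrowth
Title: Development of Sexual Dimorphism in the Petrous-Bone Lateral Angle
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study how sexual dimorphism of the lateral angle of
    the internal acoustic meatus emerges during childhood. Provides cohort
    ingestion with exclusion rules and descriptive summaries, a synthetic
    four-collection cohort generator with a logarithmic cranial-breadth
    growth model and a pubertal dimorphism ramp, ordinary least-squares
    model suites with Holm-corrected inference, ROC/AUC and fixed cut-off
    sex classification, and a bootstrap procedure that localizes the age
    window in which male and female biauricular-breadth growth diverge:
    sex-stratified LOESS curves, stratified resampling of the female-male
    difference curve, pointwise BCa confidence bands, and divergence-window
    detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), boot, pROC, optparse, withr
Config/testthat/edition: 3
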