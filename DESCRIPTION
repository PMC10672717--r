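Package: uceisr
Title: Interobserver Consensus and Image Preprocessing for Endoscopic
    Ulcerative Colitis Severity Grading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-expert grading of ulcerative colitis severity
    from endoscopic images with the Ulcerative Colitis Endoscopic Index of
    Severity (UCEIS).  Implements majority-vote consensus labelling over
    rater panels, interobserver agreement statistics (two-way random-effects
    intraclass correlation and Fleiss' kappa) from first principles with
    interpretation bands, HSV-threshold detection of specular reflections
    and unlit dark regions with diffusion inpainting, a seeded affine
    augmentation recipe, a desk-scale convolutional classifier with a full
    evaluation report, and a synthetic-data generator that produces
    endoscopic-like frames with ground-truth artifact masks and simulated
    expert panels with tunable agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
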