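Package: flymag
Title: Tracking and Statistics for Drosophila Magnetosensitivity Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for large-scale behavioural screens of magnetic-field
    effects in Drosophila. Implements the video-tracking algorithm used for
    negative-geotaxis climbing assays (two-pass background estimation,
    per-frame intensity scaling, grayscale morphological opening and
    geometry-gated blob detection), the climbing statistics (climber
    proportions, proportion and mean-height timecourses, repeated-measures
    ANOVA, binomial GLMM and linear mixed models of exposure effects), the
    T-maze binary-choice statistics (preference index, binomial/quasi-binomial
    and beta-binomial group tests, Cohen's h, analytic power and sample-size
    calculations), a deliberately pseudoreplicated per-fly test for
    methodological comparison, and synthetic-data generators (beta-binomial
    choice counts with intraclass correlation; rendered climbing videos with
    ground truth) so that every stage can be validated against known answers.
    Includes experimenter-blinding utilities and a reproducible pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    lme4,
    lmerTest,
    car,
    glmmTMB,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
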