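Package: tearfilm
Title: Tear-Film Breakup Time Estimation and Dry Eye Diagnosis from
    Fluorescein Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the tear-film breakup time (TFBUT) from blue-light
    fluorescein anterior-segment video and applies the revised Asia Dry Eye
    Society criteria (TFBUT of 5 seconds or less together with an OSDI
    symptom score over 13) to classify eyes as dry eye disease or not.
    Provides a seeded synthetic fluorescein-video simulator with full ground
    truth, frame preprocessing (0.2-second slicing, quality exclusion,
    corneal region detection, 384x384 standardization), an interpretable
    dark-spot frame classifier with confidence scores plus a small trainable
    surrogate and occlusion attribution maps, blink segmentation and
    per-segment breakup timing with censoring, OSDI scoring and the
    diagnostic rule, and the evaluation statistics (confusion-table metrics,
    exact binomial and bootstrap confidence intervals, rank-statistic ROC
    AUC, Spearman correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
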