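Package: gaitgaf
Title: Gait Classification and Severity Estimation from Ground Reaction
    Forces via Gramian Angular Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing vertical ground reaction force (VGRF) gait
    recordings from pressure-sensing insoles. Per-foot force sums are segmented
    into overlapping windows, encoded as Gramian Angular Summation Field (GASF)
    images, and fed to small convolutional neural networks that classify
    parkinsonian versus control gait and regress clinical severity scores
    (Hoehn & Yahr, UPDRS, UPDRS motor, Timed Up and Go). Includes a reader and
    writer for the per-walk 16-sensor text dialect used by public gait
    archives, a synthetic gait generator with controllable cadence,
    stride-to-stride variability, asymmetry and severity linkage, a compact
    CNN engine (convolution, max-pooling, dropout, L2, Adam, plateau learning
    rate scheduling) written against base R linear algebra, subject-grouped
    stratified cross-validation, classification and regression metrics, SMOTE
    class balancing, and an exact Wilcoxon signed-rank test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
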