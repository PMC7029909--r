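Package: ovisense
Title: Lameness Detection from Ear-Mounted Inertial Sensors in Sheep
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-phase pipeline for detecting lameness in sheep from
    ear-tag accelerometer and gyroscope recordings. Simulates annotated
    sheep-day recordings with activity bouts (walking, standing, lying)
    and lameness-dependent signal structure; computes magnitude-difference
    signals, overlapping 7-second windows and 32 time- and frequency-domain
    features per window; ranks features with ReliefF; benches five
    classifiers under lameness-stratified 10-fold cross-validation; and
    evaluates sheep-level separation with the sigma-difference statistic,
    midpoint threshold and Mann-Whitney U test.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
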