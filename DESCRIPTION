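Package: nestout
Title: Nested Binary Classification for Outlier Activity Detection in
    Wearable Sensor Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects outlier (unknown) activities in human-activity
    recognition sensor streams by nested one-vs-rest elimination: streams
    are segmented into fixed-size overlapping windows, each window is
    enriched with ten per-axis signal statistics, and a cascade of binary
    classifiers (one per known activity) removes recognized records level
    by level; records surviving every level are reported as outliers.
    Includes a synthetic tri-axial stream generator with injectable
    outlier segments, readers for raw accelerometer CSV and processed
    feature tables, confusion-matrix evaluation (accuracy, precision,
    sensitivity, specificity), outlier detection and over-detection
    accounting, and a multiclass feed-forward network baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    zoo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
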