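Package: sprintgc
Title: Ground-Contact Detection in Sprint Acceleration from Shank-Mounted IMUs
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Detects ground contacts (initial contact to toe-off) in the
    acceleration phase of athletic sprints from two resultant shank-IMU
    channels at 250 Hz. The core is a per-timestep binary classifier built
    from stacked inception blocks (parallel kernel-1/3/5/7 convolutional
    branches with pointwise bottlenecks, a projected residual connection,
    batch normalization and a pointwise sigmoid head), trained with Adam on
    per-timestep binary cross-entropy and early stopping, written in
    RcppArmadillo. Around it: per-run min-max feature scaling,
    sliding-window slicing with overlap-averaged probability reassembly,
    contact postprocessing (0.5 binarization, removal of contacts shorter
    than 12 frames), event/frame agreement metrics (mean and median
    Hausdorff over transitions, event precision and recall, Rand index) and
    method-comparison statistics (Bland-Altman limits of agreement,
    Spearman, Wilcoxon signed-rank with effect size, MAPE/RMSE, step-wise
    contact-time tables, sampling-rate quantization error). A seeded
    synthetic sprint-signal generator reproduces the 12-athlete study
    design so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    car,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
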