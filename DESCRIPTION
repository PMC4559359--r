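Package: netcure
Title: Data Curation for Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Prepares incomplete and faulty datasets for network inference.
    Implements trimmed scores regression (TSR) imputation of missing values
    together with five comparison methods (iterative PCA, complete-case,
    mean, linear interpolation, nearest neighbour), PCA-based multivariate
    monitoring (Hotelling T2, square prediction error, contribution
    analysis) with a resampled 95 percent control limit for detecting and
    correcting extreme outliers, a minimal information-theoretic network
    inference engine (mutual information, entropy reduction, transfer
    entropy), and simulation benchmarks scoring precision and recall of
    recovered links under missingness and injected outliers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grid,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
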