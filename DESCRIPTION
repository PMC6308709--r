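Package: parapam
Title: Parallel Partitioning Around Medoids with Operation-Count Cost
    Accounting and Colour Image Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitioning Around Medoids (PAM) clustering with the classic
    greedy build phase and within-cluster swap phase, together with a
    deterministic simulation of its master-worker decomposition across P
    homogeneous processing elements. Every run carries an operation-count
    ledger (scalar distance-evaluation units and communication units) from
    which critical-path running time and speedup curves are derived, so the
    scalability of the parallel decomposition can be studied without
    wall-clock benchmarking. Includes colour-based image segmentation by
    clustering RGB pixels, structural similarity (SSIM) validation of
    segmented images, and seeded synthetic-data generators (uniform point
    clouds, Gaussian mixtures with controllable cluster-size balance, and
    multi-region test images).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
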