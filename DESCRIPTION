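Package: bmsmaps
Title: Group-Level Bayesian Model Selection Maps for M/EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise Bayesian model selection mapping for M/EEG data.
    Builds scalp-time voxel volumes from epoched channel data, approximates
    per-subject log model evidence at every voxel with a variational-Bayes
    general linear model, inverts a random-effects Dirichlet model over group
    model frequencies, and produces thresholded posterior probability maps
    (PPMs) and exceedance probability maps (EPMs) with cluster tables. Includes
    a synthetic-data generator with known ground truth, fixed-effects group
    Bayes factors, NIfTI input/output, and a reproducible pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    tibble,
    dplyr,
    ggplot2,
    generics,
    rlang,
    igraph,
    interp,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
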