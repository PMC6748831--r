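Package: ectostorm
Title: Nanoscale and Quantitative Analysis of Synaptic Ectosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for synaptic ectosomes (SE), the TCR-enriched
    extracellular vesicles that helper T cells deposit at the immunological
    synapse. Implements single-molecule localization (dSTORM) processing with
    photon filtering, blink merging and Gaussian rendering; stage-drift
    estimation by subset image correlation and fiducial-based channel
    registration; density-based vesicle segmentation with FWHM sizing and
    per-vesicle protein positivity classes; three two-channel colocalization
    statistics (coordinate-based colocalization, angular-averaged pair
    cross-correlation, nearest-neighbor distances) plus image-level Pearson
    correlation; MESF-calibrated flow-cytometry transfer quantification and SE
    surface-geometry estimates; and proteomic fold-change filtering with Markov
    clustering of confidence-scored interaction networks. A synthetic-data
    module simulates every input the pipeline consumes, so the full analysis is
    testable without instrument data.
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
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
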