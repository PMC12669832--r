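Package: larvasearch
Title: Quantitative Analysis of Larval Local-Search Behavior in a Circular Arena
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for Drosophila larva centroid tracks recorded in a
    circular arena: repair of detection gaps (linear, circular-arc, end-hold and
    edge-assigned interpolation), segmentation of an experiment into baseline,
    pre-search, investigation and search phases, zonal residency and track-length
    metrics, stop and center-revisit counting, a search-score preference statistic,
    and the accompanying nonparametric statistics (Wilcoxon signed-rank,
    Mann-Whitney U, Kruskal-Wallis with post hoc comparisons). Includes a
    run-and-turn agent simulator that generates arena-scale synthetic tracks with
    edge-biased and center-orbiting movement modes, stop episodes and detection
    dropout, so the whole pipeline is testable end to end without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    rlang,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
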