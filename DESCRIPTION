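Package: castmap
Title: Digital Mapping of Plaster Cast Modifications for Ankle-Foot Orthoses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how an orthotist modifies a plaster cast during
    ankle-foot orthosis fabrication. Pairs of pre- and post-modification
    triangle surface meshes (STL, PLY, OBJ) are rigidly aligned by landmark
    initialisation and trimmed iterative-closest-point registration, compared
    by a signed mesh-to-mesh distance field (positive = plaster added,
    negative = plaster removed), summarised as mean positive, negative and
    absolute differences, and rendered as diverging-colour modification maps.
    Companion statistics cover intra-rater reliability (two-way intraclass
    correlation, symmetric percentage error) and cohort associations
    (Spearman correlation with Portney strength and effect categories,
    Kruskal-Wallis tests). A synthetic-data module generates watertight
    cast-like meshes with planted, exactly known modifications, pose
    perturbations, scan-noise replicates and simulated cohorts, so the whole
    pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
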