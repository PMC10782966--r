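Package: lipidshift
Title: Differential Lipidomics and Membrane Remodeling Analysis for
    Halotolerant Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing intact-polar-lipid (IPL) profiles of
    halotolerant bacteria grown under varying salinity, hydraulic retention
    time and growth mode. Parses shorthand lipid nomenclature (including
    lyso, sum-composition, sphingoid and ambiguous dual annotations) and
    classifies headgroup net charge; normalizes LC-MS peak-intensity tables
    by total intensity or log2-median scaling; computes pairwise
    differential-abundance tables with Student's t-test and log2
    fold-change thresholds, subclass tallies and summary percentages;
    derives abundance-weighted membrane statistics (double-bond index and
    mean chain length) and per-sample charge-class composition profiles;
    and implements the multivariate workflow standard in this niche:
    Ward.D2 hierarchical clustering, two-component PLS-DA with
    leave-one-out Q2, and Monte-Carlo cross-validated random-forest
    biomarker ranking with ROC AUC. A synthetic lipidome generator with
    planted ground-truth effects makes the whole pipeline testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    rlang,
    randomForest,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
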