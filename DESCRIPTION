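Package: miRtraverse
Title: Serum-Circulating miRNA Biomarker Discovery by Traverse
    Fold-Change Consensus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery pipeline for serum-circulating miRNA prognostic
    biomarkers from whole-miRnome microarray profiles of xenograft disease
    models. Implements blank background subtraction, spike-in/U6 control
    normalization and sham baseline correction of probe intensities; the
    traverse analysis (all control-by-case fold-change comparisons followed
    by successive set intersections to a consensus candidate set at a
    2-fold cutoff); cross-species mature-sequence homology filtering to
    retain species-specific candidates and flag high-fold top markers;
    delta-delta-Ct qPCR validation with cross-platform correlation; ANOVA
    with Tukey post-hoc group comparison and percent-positivity
    quantification; and crisscross common-target consensus mining. A
    synthetic-data module generates array, catalog, qPCR, target-map and
    cell-count inputs with planted ground truth so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
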