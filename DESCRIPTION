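Package: phosphoRate
Title: Differential Phosphoproteome Analysis of Dual-Stained 2-DE Gels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistics for comparative phosphoproteomics on two-dimensional
    electrophoresis (2-DE) gels dual-stained for phosphoprotein (Pro-Q
    Diamond) and total protein (SYPRO Ruby) signal. Computes per-spot
    phosphorylation rates (PR = P/T), bias-corrected percentile bootstrap
    confidence intervals with Bonferroni adjustment for small replicate
    groups, fold-change and bounded relative-change (RC) effect statistics
    that remain defined for group-unique spots, group-level spot-count tests
    (Fisher exact, Mann-Whitney), and UPGMA clustering of significant
    phosphoproteins on RC-derived distances with Newick export. Includes
    total-valid-spot normalization, replicate-reproducibility filtering,
    protein-fragment flagging, and a synthetic dual-stain spot-table
    generator with known ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    optparse
Config/testthat/edition: 3
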