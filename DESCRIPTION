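Package: ionoscreen
Title: Analysis Pipeline for Genome-Wide Ionomic Screens in Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical analysis of high-throughput plate-based ionomic
    screens, in which element concentrations (ICP-MS, ppm) are measured for
    thousands of yeast mutant strains on 96-well plates. Provides
    control-strain plate/day normalization on the log scale, robust
    MAD-moderated Z statistics with Benjamini-Hochberg false discovery rate
    control, a replicate-consistency (annealing) filter, percent-change
    effect sizes with A/B/C effect groups, exhaustive significance
    clustering of per-element sign patterns with median profiles and
    complete-linkage heatmap ordering, hypergeometric gene-set overlap and
    conditional Gene Ontology enrichment tests, and interaction subnetworks
    annotated with ionomic profile correlations. A plate-screen simulator
    with known ground truth makes every stage testable without the original
    raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
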