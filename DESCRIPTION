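Package: splicedep
Title: Interdependence Analysis of Exon Skipping Across Splicing-Factor Knockdowns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse regulatory interdependence between SR and hnRNP
    splicing factors from skipped-exon differential-splicing tables. Reads
    rMATS-style knockdown tables, filters per-RBP affected-exon sets
    (regulons), tests every RBP pair for greater-than-chance regulon overlap
    with a hypergeometric survival function, and characterises independently
    versus interdependently regulated exon populations: direction of
    regulation, regulator multiplicity, wildtype inclusion levels, and exon
    sequence features. Includes a synthetic-data generator with planted
    ground truth (regulon sizes, pairwise overlaps, direction biases, PSI
    mixtures, feature trends) so every pipeline stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    tibble,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
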