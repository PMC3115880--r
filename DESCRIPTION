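Package: abatrans
Title: ABA-Regulated Transcriptome Analysis for Guard Cells and Leaves
Version: 0.1.0
Authors@R: person("abatrans", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Identifies abscisic acid (ABA) regulated genes from factorial
    microarray designs (two tissues, four heterotrimeric G-protein genotypes,
    with and without hormone) by intersecting a Boolean regulatory-mode
    classifier with an empirical-Bayes moderated-t linear model, and analyses
    their 1000-bp upstream regions for cis-regulatory elements: degenerate
    motif scanning, gene-level hypergeometric enrichment, positional
    distributions, exhaustive 5-10-mer discovery with dual backgrounds, and
    gene-set overlap statistics (representation factor, core sets across
    experiments). Ships a synthetic-data generator with planted truth so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
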