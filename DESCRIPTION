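Package: loxtron
Title: Design and Simulation of Targetron-Delivered Cre-lox Genome Editing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico toolkit for planning bacterial genome editing with
    retargetable mobile group II introns ("targetrons") that deliver lox sites
    for Cre-mediated rearrangement. Models the algebra of 34-nt lox sites
    (linker specificity classes and lox66/lox71 arm mutants), annotated
    circular and linear DNA molecules, and Cre-mediated excision, inversion,
    and integration alongside host homologous recombination between intron
    scaffolds. Designs lox-cargo inserts with RNA-structure flexibility
    scoring, intron retargeting fragments and primers, and diagnostic PCR
    verification plans with exact in-silico PCR across wild-type, uninduced,
    and induced strain states. Includes seeded synthetic-fixture generators
    for genomes and plate-reader growth curves, and a windowed-R-squared
    doubling-time estimator for fitness measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
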