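Package: gsflow
Title: Genome Size and GC Content from Internal-Standard Flow Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates nuclear genome size (C-values) of animal specimens from
    fluorescence histograms recorded with an internal plant standard, infers
    genomic GC content from paired AT-selective (DAPI) and intercalating (PI)
    dye measurements via a fluorochrome binding-length model, runs the
    comparative statistics used in insect genome-size surveys (Kruskal-Wallis
    and pairwise Mann-Whitney tests across chromosome-number groups, sex
    differences as X-chromosome size, GC contrasts among families), and
    reconstructs ancestral genome sizes on a phylogeny by maximum likelihood
    under Brownian motion. Includes seeded generators for synthetic
    histograms, dye pairs, trees and trait data so the whole workflow is
    testable without instrument output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
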