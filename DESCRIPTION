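Package: loopchron
Title: Phylogenomic Chronologies of Protein Loop Prototypes and Structural Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to retrace the evolutionary history of protein loop
    prototypes and structural domains from genomic-abundance censuses.
    Abundances of domain families across proteomes of Archaea, Bacteria,
    Eukarya and viruses are encoded as linearly ordered multistate
    phylogenetic characters, most-parsimonious trees of domains are inferred
    under Wagner (linear-cost Sankoff) parsimony, rooted by Lundberg
    ancestor attachment, and converted into node-distance chronologies
    calibrated in billions of years. Loop prototypes are attached to dated
    families, classified as modular or non-modular, and summarised as
    four-set Venn-group accretion tables across six evolutionary phases,
    including urancestor (LUCA/LUCellA) repertoires. Companion tools
    quantify reticulate versus vertical signal (quartet delta scores,
    Q-residuals, neighbor-joining with bootstrap support) and compute
    ArchDB-style internal coordinates (D, hoist, packing, meridian) of
    supersecondary loop motifs. A seeded synthetic-data generator provides
    censuses, prototype mappings, annotations and loop coordinates with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    bio3d,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
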