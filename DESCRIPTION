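Package: cladesig
Title: Clade-Specific Signature Proteins and Conserved Signature Indels
Version: 0.1.0
Authors@R:
    person("Alex", "Marchand", email = "alex.marchand@example.org",
           role = c("aut", "cre"))
Description: Discovery of clade-specific signature proteins (CSPs) and
    conserved signature indels (CSIs) from comparative genomic data, and
    mapping of their evolutionary origins onto a rooted phylogenomic tree.
    Implements the homology-hit taxonomic-exclusivity decision procedure for
    CSP calling (significance ceiling, E-value gap, length check, plastid and
    isolated-species exceptions, ORFan exclusion), a conserved-indel scanner
    for protein alignments with flank-conservation checks and outgroup
    polarization, Dollo gain/loss parsimony on presence/absence matrices, and
    a supermatrix neighbour-joining stage (alignment concatenation,
    Gblocks-style block filtering, Kimura protein distances, bootstrap
    support, outgroup rooting). A fully seeded synthetic-data generator with
    machine-readable ground truth makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
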