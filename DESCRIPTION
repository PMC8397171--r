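Package: lepmito
Title: Comparative Accounting of Lepidopteran Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Annotation-driven comparative analysis of circular insect
    mitochondrial genomes: coordinate arithmetic and validation over
    37-gene annotations, base-composition and skew accounting, codon-usage
    statistics (RSCU and codons-per-thousand under the invertebrate
    mitochondrial code), a signed intergenic/overlap junction ledger with
    conserved-motif detection, dissection of the A+T-rich control region
    into its conserved elements (origin motif, poly-T, microsatellite,
    tandem repeat, poly-A), and a 13-gene supermatrix stage with K2P
    distances, neighbour-joining trees and monophyly queries. Ships a
    seeded synthetic-mitogenome generator so every stage is testable
    against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
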