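Package: cbmca
Title: Identification and Classification of Cyanobacterial Metacaspases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for genome-wide identification of
    metacaspases in bacterial proteomes: iterative homology search with
    affine-gap local alignment and Karlin-Altschul E-values, detection of
    the caspase catalytic subunit P20 (CASc) domain and ten accessory
    domain types from packaged profile models, His/Cys catalytic-dyad
    scanning with a substitution taxonomy, alpha/beta family and subfamily
    classification, per-strain comparative summaries, and neighbor-joining
    phylogenies of the catalytic domain with bootstrap support. Ships the
    published 58-gene metacaspase census of 33 cyanobacterial genomes as a
    plain-text fixture and a synthetic proteome generator with planted
    metacaspases for end-to-end testing without any network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
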