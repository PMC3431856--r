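Package: mitomoth
Title: Architecture, Composition and Phylogenetic Analysis of Insect
    Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for describing annotated circular mitochondrial genomes of
    insects, with an emphasis on the lepidopteran gene arrangement. Computes
    the junction ledger of intergenic spacers and gene overlaps around the
    circle, nucleotide composition with AT/GC strand skews per genome region,
    codon usage and relative synonymous codon usage (RSCU) under the
    invertebrate mitochondrial code, structural scans of the A+T-rich control
    region (replication-origin signature, tandem repeats, microsatellites,
    flanked stem-loops, diagnostic motifs), constrained cloverleaf folding of
    annotated tRNA genes, and concatenated-protein phylogenetics (neighbor
    joining, Fitch parsimony with nearest-neighbor-interchange search, and
    nonparametric bootstrap with majority-rule consensus). A synthetic-genome
    generator plants known structure so every stage can be tested without
    external downloads. Results are returned as tibbles and trees as 'ape'
    phylo objects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
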