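Package: mitoarch
Title: Mitochondrial Genome Architecture, Strand Skew and Recoding Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of animal (especially chelicerate)
    mitochondrial genome architecture. Reads annotated mitogenomes from GenBank
    flat files or FASTA + gene tables with circular-coordinate support; computes
    AT and CG strand-compositional skew at every reporting granularity (whole
    major strand, per gene, per codon position, pooled across protein-coding
    genes) with the minor-strand complementation rule; classifies gene-order
    rearrangements (translocation, strand inversion) against the ancestral
    chelicerate arrangement; produces recoded phylogenetic matrices
    (invertebrate-mitochondrial-code translation, back-translation to codon
    alignments, RY, Neutral-Transitions-Excluded and six-group physiochemical
    recoding); and simulates annotated mitogenomes with known compositional and
    rearrangement ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
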