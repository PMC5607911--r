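Package: shellcand
Title: Candidate-Gene Discovery for a Dominant/Recessive Shell-Colour
    Polymorphism from Transcriptome Variants and Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to prioritise candidate transcripts underlying a
    dominant/recessive colour polymorphism from tissue RNA-seq of a small
    pedigree-free sample of individuals. Implements hard variant filters
    (Fisher-strand, quality-by-depth, SNP-cluster and per-sample depth),
    classification of single-nucleotide variants against open reading
    frames, a segregation filter that keeps variants consistent with a
    dominant/recessive morph model, a negative-binomial exact-test
    differential-expression stage with TMM normalisation, and a RAD-tag
    consensus-extension and ungapped seed-and-extend search with
    Karlin-Altschul E-values. A fully synthetic study generator with a
    planted-truth table supports parameter-recovery testing of the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    vcfR,
    ape,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
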