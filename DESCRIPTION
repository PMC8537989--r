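Package: tercits
Title: Discovery and Break-Site Typing of Telomerase-RNA-Flanked Interstitial Telomeric Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects interstitial telomeric sequences flanked by fragments
    retrotranscribed from the telomerase RNA component (TERC-ITS loci) in
    genomic sequence. Implements a deterministic seed-and-extend local
    aligner with blastn-style affine-gap scoring (word size 11, +2/-3,
    gap open 5 / extend 2), a tandem telomeric-hexamer array scanner,
    structural classification of each locus (fragment position and
    orientation relative to the repeat array, TERC domain of origin,
    in-frame 3' extension), and comparison against orthologous "empty"
    loci to type the double-strand-break repair signature at the
    insertion junction (deletion, random insertion, microhomology). A
    seeded synthetic-genome generator plants loci with full ground truth
    so every stage is testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    IRanges,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stringr,
    tibble,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
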