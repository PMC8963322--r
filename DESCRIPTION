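Package: herivome
Title: Small RNA Profiling and Phylogeographic Dating of Inherited Insect Viromes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising vertically transmitted (inherited) RNA
    viruses of insects from small-RNA sequencing data. Implements a
    strand-aware short-read mapper with a minimum match-fraction threshold,
    per-contig small-RNA size profiles with a 21-nt siRNA enrichment call,
    positional nucleotide-frequency matrices and exact binomial tests for the
    piRNA ping-pong signature (antisense U1, sense A10), disambiguation of
    reads between an endogenous viral element (EVE) and its exogenous
    counterpart via perfect-identity windows and ambiguity masks, and
    distance-based phylogeography (uncorrected p-distances, neighbor-joining,
    Robinson-Foulds/Mantel congruence, COI molecular-clock dating, and
    prevalence arithmetic). A seeded simulator generates every input the
    pipeline consumes with the statistical structure these analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    ape,
    jsonlite,
    phangorn,
    rtracklayer,
    stats,
    utils,
    vegan,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
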