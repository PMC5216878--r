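Package: beanscan
Title: Domestication Scans from Multi-Locus Sequence Diversity in Common Bean
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genetic analysis of wild versus domesticated sequence
    panels: per-locus nucleotide diversity (pi, Watterson's theta), haplotype
    statistics and loss-of-diversity summaries; shared/private polymorphism
    partitioning with synonymous/nonsynonymous classification and modified
    Nei-Gojobori dN/dS with Jukes-Cantor correction; Hudson FST with permutation
    tests and two-level AMOVA; a composite selection-index scan tested against
    coalescent simulations under explicit domestication-bottleneck demographies;
    and an FDIST-style FST-outlier test for biallelic SNP panels. Includes a
    seeded synthetic-data generator emulating a 49-locus wild/domesticated
    resequencing design with known injected sweeps, so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
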