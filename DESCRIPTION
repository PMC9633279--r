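Package: sweepscan
Title: Selective-Sweep Scans and Deletion-Trait Association for
    Two-Population Resequencing Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Windowed population-genetic statistics (nucleotide diversity,
    Weir-Cockerham Fst, Tajima's D), Z-transformed joint top-quantile
    outlier calling for selective-sweep detection between two populations,
    candidate-gene annotation around sweep regions, linkage-disequilibrium
    decay, individual-level p-distance neighbor-joining trees, genotype
    frequency tables, and dosage-coded linear-model trait association with
    sex and batch covariates and an optional two-locus interaction.
    Includes a synthetic two-population dataset generator (Balding-Nichols
    background differentiation, a planted sweep, and trait-linked deletion
    loci) so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
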