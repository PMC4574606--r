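Package: aeqc
Title: Allele-Specific Expression Counting and Quality Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring allelic expression (AE) from RNA-seq at
    heterozygous SNPs: filtered allele counting from aligned reads with
    duplicate removal, unbiased duplicate-representative selection and
    single counting of overlapping mate pairs; detection of genotyping
    errors via a binomial test against an empirically estimated
    sequencing-noise rate; AE effect sizes and exact binomial tests
    against the classic 0.5 null or a bias-adjusted global null with
    false-discovery-rate control, effect-size cutoffs and depth scaling;
    between-sample AE distances with classical multidimensional scaling;
    gene-level AE comparison between eQTL heterozygotes and homozygotes;
    and a read-level simulator with known truth (allelic ratios, noise,
    duplicates, mate overlap, genotyping errors, reference mapping bias)
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    cluster,
    jsonlite,
    optparse
Config/testthat/edition: 3
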