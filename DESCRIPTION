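Package: genocrypt
Title: Privacy-Preserving GWAS Statistics and Genome Distances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for privacy-preserving computation over human genomic
    data in the semi-honest model: secure outsourcing of case-control GWAS
    statistics (minor allele frequency and the allelic chi-square test)
    under additively homomorphic Paillier encryption; two-party secure
    computation of pooled GWAS statistics via additive secret sharing and
    of genome Hamming / approximate edit distances via Diffie-Hellman
    private set intersection cardinality; the set-difference approximation
    of edit distance over VCF variant sets with an exact Levenshtein
    oracle for validation; a synthetic benchmark generator emulating
    case/control genotype panels, paired genome variant sets and mutated
    genomic segments; and an evaluation harness reporting accuracy,
    timing, storage and communication cost.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: OpenSSL (libcrypto >= 1.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
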