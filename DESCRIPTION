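Package: scphylo
Title: Maximum Likelihood Cell Phylogenies from Single-Cell SNV Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phylogenetic inference for single-cell DNA sequencing data.
    Models diploid single-nucleotide-variant genotypes with a 16-state
    (phased) or 10-state (unphased) time-reversible Markov substitution
    model, combined with an explicit observation model for allelic dropout
    and amplification/sequencing error. Provides Felsenstein-pruning
    likelihood computation with genotype, genotype-likelihood, or
    Phred-scaled (PL) tip inputs, maximum-likelihood estimation of model,
    branch-length and error parameters, SPR tree search from parsimony and
    random starting trees, standard and transfer bootstrap branch support,
    Robinson-Foulds tree comparison, marginal ancestral genotype
    reconstruction with per-branch mutation mapping, and a coalescent
    simulator of single-cell genotype and read-count data for benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Matrix,
    vcfR,
    seqinr,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
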