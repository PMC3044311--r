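Package: ldgeno
Title: LD-Aware Genotype Calling from Low-Coverage Sequencing Pileups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls diploid SNP genotypes from low-coverage shotgun read
    pileups by combining per-locus genotype likelihoods with linkage
    disequilibrium information extracted from a phased reference panel.
    Two founder-haplotype hidden Markov models (maternal and paternal),
    trained by Baum-Welch on the panel, are coupled in a hierarchical
    factorial HMM whose paired haplotype emissions sum to the genotype;
    genotypes are called by forward-backward posterior decoding in
    O(m + n K^3) time. Includes LD-oblivious single-SNP Bayesian and
    binomial-test baselines, a seeded mosaic-haplotype read simulator,
    exhaustive-enumeration oracles for small instances, and a
    concordance evaluation harness with no-call thresholding, coverage
    downsampling and reference-allele-bias diagnostics.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
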