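Package: edriver
Title: Simulation and Inference for Self-Eliminating X-Linked Allelic Drives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward population-genetic simulation and Bayesian inference for a
    unitary self-eliminating CRISPR allelic drive ("e-Drive") carried at the
    X-linked yellow locus of Drosophila melanogaster, driving the wild-type
    1014L allele of the voltage-gated sodium channel (vgsc/para) against the
    insecticide-resistant kdr 1014F allele. Provides exact discrete-generation
    genotype-frequency recursions and finite-population stochastic cage
    simulations under CRISPR germline conversion, lethal mosaicism, maternal
    Cas9 carryover and mating/fecundity fitness costs; an observation model
    matching laboratory cage scoring (half-population dominant-marker counts
    and pooled-fly amplicon sequencing); Metropolis-Hastings fitting of the
    drive parameters with uniform priors; empirical estimators for
    cross-based conversion rates and transmission bias; a deterministic
    amplicon-read classifier for L/F/NHEJ allele calling; and synthetic-data
    generators for cage observations and amplicon reads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    Biostrings
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
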