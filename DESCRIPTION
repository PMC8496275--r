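Package: PopGenFlux
Title: Polymorphism, Divergence and Codon-Usage Tests of Selection for
    Multi-Species Alignments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Molecular population-genetics toolkit for codon-structured
    multi-species nucleotide alignments. Computes per-site-class diversity
    and divergence summaries (Watterson's theta, pi, uncorrected divergence,
    Tajima's D, Fay and Wu's H), obtains empirical p-values for
    site-frequency-spectrum tests from a built-in Hudson-style coalescent
    simulator with recombination and flexible demography (equilibrium,
    exponential growth, multi-epoch bottlenecks) under uniform parameter
    priors, builds McDonald-Kreitman 2x2 tables (single-species, combined
    polymorphism, and low-frequency-variant filtered), performs the
    preferred/unpreferred codon substitution flux (CF) test along lineages
    assigned by outgroup parsimony, and maps amino-acid substitutions onto a
    species tree by Fitch parsimony with region-heterogeneity tests.
    Includes seed-deterministic synthetic-data generators with complete
    truth logs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
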