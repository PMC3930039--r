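Package: racecaps
Title: Race-Diagnostic CAPS Markers and Hybrid-Zone Population Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Design and analysis toolkit for cleaved amplified polymorphic
    sequence (CAPS, PCR-RFLP) markers that diagnose the E- and Z-pheromone
    races of the European corn borer (Ostrinia nubilalis) from the pgfar
    (pheromone gland fatty-acyl reductase) locus. Covers alignment-level
    diversity statistics (nucleotide diversity, Tajima's D sliding-window
    scans), fixed-difference SNP discovery, in-silico PCR and restriction
    digestion, fragment-pattern genotype calling, genotype-phenotype
    association, and hybrid-zone population genetics: observed and Nei
    unbiased expected heterozygosity, exact conditional Hardy-Weinberg
    tests by enumeration and by Markov chain, Weir-Cockerham hierarchical
    F-statistics and AMOVA with permutation tests, pairwise F_ST, and
    Benjamini-Yekutieli multiple-testing thresholds. Includes seeded
    synthetic-data generators for sequence panels, population genotype
    samples and pheromone phenotypes so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
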