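Package: matloci
Title: Balancing Selection and Mating-Type Diversity at Fungal Tetrapolar Mating Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying long-term balancing selection at the mating
    loci (MATA, MATB) of tetrapolar basidiomycete fungi from per-gene
    multi-species sequence alignments. Provides a two-species coalescent
    simulator for neutral and trans-species balanced loci, per-gene
    population-genetic statistics (nucleotide diversity, dxy, Hudson's Fst,
    Tajima's D, Nei-Gojobori dN/dS), a multilocus Hudson-Kreitman-Aguade
    test with per-locus partial contributions, amino-acid-identity allelic
    class clustering with phylogenetic concordance checks, mating-type
    enumeration and cross-compatibility prediction, a CaaX/CpaX
    pheromone-precursor scanner, and a genome-wide outlier scan combining
    all statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
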