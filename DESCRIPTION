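Package: repeatscape
Title: Repeat Landscapes, Microsatellite Seeding and LINE Life History from
    Genome Sequence and Shotgun Reads
Version: 0.1.0
Authors@R: person("Repeatscape", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies microsatellite (SSR) and transposable-element (TE)
    landscapes of assembled genomes, tests whether specific TE families seed
    new microsatellite loci via their 3' tails using resampled genomic
    backgrounds and one-tailed exact tests, builds LINE consensus sequences
    from unassembled shotgun reads by iterative mapping and majority rule,
    profiles LINE 5' truncation (3':5' read-depth ratio) and element age
    (subfamily-filtered pairwise divergence), and runs the
    phylogenetic-comparative statistics (independent contrasts, censored
    Brownian-motion rate tests, ancestral states, Kruskal-Wallis/Dunn) used
    to test demographic explanations of repeat-content variation. Includes a
    synthetic-genome simulator with truth tables so every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
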