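Package: nitroguild
Title: Genome-Resolved Nitrogen-Cycle Guild and Auxotrophy Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers functional structure of nitrogen-removing microbial
    communities from per-genome gene annotations. Starting from
    metagenome-assembled genome (MAG) annotation and quality tables, the
    package filters annotation hits, applies quality control and
    dereplication, calls biosynthetic and carbon-fixation pathway presence
    with a one-missing-step completeness heuristic, censuses nitrogen-cycle
    marker genes, assigns functional guilds (aerobic and anaerobic ammonia
    oxidizers, nitrite oxidizers, comammox, denitrifiers, DNRA), derives a
    community-level producer/consumer exchange network over nitrogen-oxide
    intermediates, profiles amino-acid and B-vitamin auxotrophies and their
    complementarity, and screens sequencing reads against marker-gene
    references with identity and coverage thresholds reported as reads per
    million. Ships a 55-MAG partial nitritation/anammox community fixture
    and a seeded synthetic-community and read simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    yaml,
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
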