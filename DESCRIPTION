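Package: RepliFire
Title: Replication Origin Firing, Checkpoint Stress, and Quantitative
    Fitness Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the intra-S-phase checkpoint control of
    replication origin firing in budding yeast. Builds S/G1 copy-number
    replication profiles from binned sequencing coverage, smooths them with
    a Fourier low-pass filter, calls replication peaks and fired origins,
    and summarises interorigin distances and peak widths. Maps
    replication-normalized DNA-damage (gamma-H2A) ChIP signal around
    origins, classifies flanking gene-pair orientation (convergent versus
    nonconvergent) and bins enrichment by replication timing. Implements
    quantitative fitness analysis (QFA) of genome-wide screens: logistic
    growth fitting, MDP/MDR fitness, population-model genetic-interaction
    scores with enhancer/suppressor calling and protein-complex
    enrichment. Includes plasmid-loss and catenane-distribution
    statistics, and a synthetic-data generator that simulates origin
    firing under checkpoint control so every stage is testable with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    minpack.lm,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
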