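Package: islandscape
Title: Promoter Islands in Bacterial Genomes: Detection, 5'-End Read
    Classification and DNA Shape Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying promoter islands, the unusually dense clusters
    of predicted transcription start points (TSPs) found in the Escherichia
    coli chromosome. Calls islands from stranded TSP tracks with a sliding
    density criterion (at least 8 TSPs per 100-bp window sustained over at
    least 300 bp); classifies 44-nt 5'-end RNA-seq reads by stepwise maximal
    genomic prefix matching with fractional multi-site attribution and
    adapter-confirmed short-oligo calling; builds wedge-model 3D duplex
    trajectories from dinucleotide step parameters and computes conformational
    chain metrics (contour and end-to-end length, bending and torsion angles,
    cumulative twist, stacking energy); and provides region-level statistics
    (binding occupancy rules, Monte-Carlo overlap null models and a
    substitution/deamination classifier for pairwise alignments). Ships a
    machine-readable copy of the 78-island annotation table and fully seeded
    synthetic-data generators so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
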