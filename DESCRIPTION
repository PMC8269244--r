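Package: metashallow
Title: Homology-Based Taxonomic and Functional Profiling of Shallow Shotgun Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained computational core for shallow shotgun
    metagenomics profiling. Builds curated, taxonomically revised and
    dereplicated reference genome databases (ANI-based species
    reclassification, near-identical genome removal, kingdom-specific
    contig length floors, host-sequence decontamination), classifies
    reads and assembled contigs by best local-alignment hits with least
    common ancestor resolution of ties and genome-size-normalized
    abundance profiles, profiles carbohydrate-active enzyme style
    functional families with pathway rollups, and evaluates profilers
    with the deviation-from-expected-abundance (DExA) index, confusion
    rates under database ablation, and sequencing-depth titrations.
    Includes seeded simulators for synthetic genomes, Illumina
    paired-end reads and Nanopore-like long reads with ground-truth
    manifests, a built-in Smith-Waterman aligner for small instances,
    and a fast k-mer seeded aligner for whole read sets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
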