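Package: magderep
Title: Dereplication of Metagenome-Assembled Genome Bins with Merging and
    Containment-Based Reassembly
Version: 0.1.0
Authors@R:
    person("magderep", "developers", email = "magderep@example.org",
           role = c("aut", "cre"))
Description: Clusters near-identical genomic bins recovered from different
    metagenomic samples by average nucleotide identity (ANI), using
    single-linkage connected components and exact maximal-clique detection,
    then selects or constructs the best bin per genome cluster. Where no
    member of a cluster passes the high-quality gate (completeness > 90,
    contamination < 5), member bins are merged and deduplicated by k-mer
    containment, so that pure but incomplete bins contribute their unique
    genomic regions instead of being discarded. ANI is estimated internally
    with a FracMinHash containment sketch, or loaded from an external
    ANI tool's edge list. Includes a fully labelled synthetic-data
    generator for end-to-end testing without external downloads, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
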