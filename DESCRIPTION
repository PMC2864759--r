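Package: replicomp
Title: Comparative Analysis of Multipartite Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative genomics of bacteria with multipartite
    genomes (several chromosomes and megaplasmids). Implements windowed
    GC-content and GC-skew profiling with replication origin/terminus
    prediction, degenerate consensus motif scanning (DnaA boxes, RepA
    repeats) on circular replicons with a mismatch budget, Smith-Waterman
    based reciprocal-best-hit orthology with identity and coverage
    thresholds, ortholog-count replicon distance matrices with
    single-linkage clustering and Newick export, within-genome paralog
    family construction by symmetrified transitive closure of a similarity
    graph, synteny block (synton) detection from conserved gene order,
    and annotation summary statistics. A seeded synthetic-data generator
    plants origins, motifs, orthologs and paralog families with known
    ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    igraph,
    ape,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
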