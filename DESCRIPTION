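Package: uvigcurate
Title: Curation of Uncultivated Viral Genomes: Circularity, vOTU
    Clustering, Completeness and Host Assignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for curating viral contigs assembled from shotgun
    metagenomes. Detects direct and inverted terminal repeats to flag
    putative complete (circular) genomes; computes pairwise average
    nucleotide identity (ANI) and aligned fraction (AF) and clusters
    sequences into viral operational taxonomic units (vOTUs) by single
    linkage at 95% ANI / 85% AF; affiliates contigs to taxa from marker
    gene hits, filters false-positive circular contigs, predicts genome
    sizes from genus-level groups and assigns completeness-based quality
    tiers; scores viral protein families for host-domain uniformity and
    classifies contigs as prokaryotic or eukaryotic viruses; and predicts
    specific hosts by vOTU co-membership with labelled genomes and by
    CRISPR spacer matching. Deterministic synthetic-data generators allow
    every step to be exercised without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
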