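Package: metasym
Title: Symbiont Metagenome Binning, Strain Variation, and Biosynthetic
    Gene Cluster Family Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing host-associated bacterial symbiont
    communities from shotgun metagenomes, modelled on the analysis of
    shipworm (Teredinidae) gill symbionts. Matches metagenome contig bins
    to cultivated isolate genomes by fragment-based average nucleotide
    identity (gANI) and alignment fraction (AF), profiles community
    composition from read mapping under an explicit seed/substitution/indel
    contract, quantifies within-species strain variation from fixed-width
    marker-gene SNP windows, clusters biosynthetic gene clusters (BGCs)
    into gene cluster families (GCFs) via bidirectional and refined
    single-directional homology networking, scores GCF occurrence across
    specimens with translated searches, and estimates the true number of
    distinct BGCs from fragmented metagenomic evidence. Includes a full
    synthetic-data module that generates every input class with known
    ground truth for hermetic testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
SystemRequirements: NCBI BLAST+ (blastp, tblastn, makeblastdb on PATH)
Config/testthat/edition: 3
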