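Package: eccTools
Title: Junction-Based Detection and Fragmentomic Analysis of Cell-Free
    Extrachromosomal Circular DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies extrachromosomal circular DNA (eccDNA) loci from
    paired-end alignments by split-read junction pinning with outward-pair
    corroboration, and analyses their fragmentomic properties: abundance per
    million mappable reads (EPM), 1-bp size profiles with peak-cluster AUC
    and AUC-ratio statistics, genomic-element enrichment against a
    Monte-Carlo expectation, junctional trinucleotide motifs, and
    strain-SNP-based fetal/maternal partitioning for mouse pregnancy
    models. Includes a fully deterministic synthetic-data generator (toy
    genomes, strain SNP tables, circle populations with bimodal 10-bp-comb
    size laws, junction-bearing pre-aligned reads in tagmentation and
    rolling-circle styles) and nonparametric group statistics
    (Kruskal-Wallis with tie correction, Dunn post hoc, Wilcoxon rank-sum
    with exact small-sample branch).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
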