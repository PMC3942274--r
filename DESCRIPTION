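Package: chondriomics
Title: Comparative Analysis of Heteroplasmic Plant Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing plant mitochondrial genomes (chondriomes) that
    exist as stoichiometric mixtures of genome variants (mitotypes). Calls
    heteroplasmic SNPs from read pileups with minor-allele-fraction and depth
    thresholds, clusters them into high-density HSNP blocks, finds homologous
    regions between consensus genomes and calls inter-genome substitution SNPs
    with coding-change annotation, analyses gene-order synteny and breakpoint
    (rearrangement) distance on signed circular gene orders, scans open reading
    frames with species-uniqueness classification and chimeric-ORF
    decomposition, and ships a synthetic chondriome simulator (mitotype
    mixtures, 454-like single-end reads, complete truth tables) for validating
    the whole pipeline against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    data.table,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
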