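Package: carpmap
Title: Growth-Trait Gene Mapping in a Full-Sib Fish Family by Pooled Fst
    Scanning and Amplicon Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping growth-trait loci in a single full-sib fish
    family with a bimodal phenotype distribution. Implements a pooled
    bulked-segregant Fst scan from per-site allele counts (nucleotide
    diversity based Fst with read-support and coverage filters and
    exon/promoter candidate annotation), dual-barcode demultiplexing of
    pooled paired-end amplicon reads, amplicon allele pileup and diploid
    genotype calling with minor-allele-frequency and call-rate filters,
    single-marker mixed-linear-model association with a centered-IBS
    kinship and variance components estimated once under the null, and
    genotype / two-locus genotype-combination effect summaries that rank
    dominant genotypes by the proportion of individuals exceeding a body
    weight threshold. A synthetic full-sib family generator with a major
    and a helper growth locus, binomially sampled pool read counts and
    barcoded paired amplicon reads makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    withr,
    ggplot2,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
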