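Package: mitotrx
Title: Transcription-Unit Annotation and Co-Evolution Analysis for Fungal Mitogenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates transcription of circular, AT-rich fungal mitochondrial
    genomes: extracts intergenic regions and composition statistics, scans
    degenerate IUPAC consensus and position-weight-matrix promoter motifs,
    locates 5'-TAAATT-3' terminator motifs downstream of mRNA and rRNA genes,
    segments the circle into polycistronic transcription units anchored at
    promoter "+1" transcription start sites, and applies the tRNA punctuation
    model to derive mature transcripts. Includes in-silico PCR, a mirror-tree
    co-evolution statistic for protein pairs (distance matrices, neighbor
    joining, matrix correlation), and a synthetic-mitogenome simulator with
    planted signals and full truth records so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    stringr,
    jsonlite,
    generics,
    ggplot2,
    Biostrings,
    BiocGenerics,
    rtracklayer,
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
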