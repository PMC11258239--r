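Package: sixmac
Title: Dual 6mA and 5mC Methylome Characterization for Fungal Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize genomes that carry both N6-methyladenine
    (6mA) and 5-methylcytosine (5mC). Filters single-molecule 6mA calls,
    classifies strand symmetry at ApT dinucleotides, detects methylated
    adenine clusters (MACs) by a density-times-efficiency distance scan,
    summarizes flanking sequence contexts into position frequency matrices
    and IUPAC consensus strings, computes observed/expected enrichment over
    genomic features, builds scaled metagene profiles, computes weighted
    bisulfite methylation levels by cytosine context, and integrates
    methylation features with gene expression (quartile stratification,
    MAC gain/loss, per-site ratio shifts with Welch tests, Fisher term
    enrichment). A seeded simulator generates complete synthetic methylomes
    in a high/symmetric/clustered regime and a low/asymmetric/scattered
    regime, with truth bundles for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
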