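Package: lnctf
Title: Transcription Factor Enrichment for lncRNA Gene Sets from ChIP-Seq Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Associates ChIP-Seq transcription-factor peak datasets with the
    regulatory regions of long noncoding RNA (lncRNA) genes and transcripts,
    and identifies transcription factors whose peaks are significantly
    over-represented around a user-supplied lncRNA set via an upper-tail
    hypergeometric test with Benjamini-Hochberg correction. Provides
    strand-aware transcription start site windows over GTF annotations,
    readers for ENCODE narrowPeak/broadPeak/BED peak files with experiment
    metadata, fast interval overlap targeting, TF-to-lncRNA and lncRNA-to-TF
    retrieval, a seeded synthetic fixture generator with known ground truth,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
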