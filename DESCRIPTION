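Package: mycnfunnel
Title: Nomination of Cell-Surface Immunotherapy Targets in MYCN-Amplified Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable implementation of a target-nomination funnel for
    MYCN-amplified neuroblastoma: stratified differential-expression screening
    on count and array-intensity platforms (log-CPM transformation with
    mean-variance precision weights and an empirical-Bayes moderated t-test),
    plasma-membrane designation from subcellular-localization confidence
    scores, detection of transcription-start-site-proximal E-box motifs,
    intersection with MYCN ChIP-seq peak occupancy, and normal-tissue and
    secretion filters. Includes negative-binomial cohort, promoter, peak-set
    and annotation simulators so the whole pipeline is testable without
    external downloads, readers and writers for the tab-separated, narrowPeak,
    BED and FASTA formats involved, and tidy accessors and plots for every
    result type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
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
    tidyr
Suggests:
    jsonlite,
    limma,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
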