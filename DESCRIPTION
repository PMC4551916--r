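Package: cistra
Title: Integrative Cistrome, Epigenome and Transcriptome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Annotates gene promoter windows with transcription-factor
    binding, histone-mark, open-chromatin and CpG-methylation states,
    tests sub-cistrome gene sets for shifted expression against bootstrap
    resampling nulls, correlates binned binding signal with expression
    along an 81-bin metagene model, and ranks drugs whose
    sensitivity-correlated gene sets (NCI-60 style panel matrices) are
    enriched in a cistrome.  A synthetic-data generator with planted
    effects makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    car,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
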