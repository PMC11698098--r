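Package: crossfeedr
Title: Purine and Pyrimidine Cross-Feeding Analysis for Marine Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies purine and pyrimidine exudation budgets in
    picocyanobacterial cultures and infers niche partitioning of purine and
    pyrimidine usage among heterotrophic bacterioplankton. Provides
    extraction-efficiency-corrected exometabolite budgets normalized to DNA
    base incorporation, completeness-aware genome trait frequency analysis
    with phylometabolic presence/absence matrices, metagenomic gene-per-genome
    frequency estimation via single-copy ribosomal protein normalization,
    diel transcriptome phase analysis, growth and flow-cytometry assay
    summaries with exact tests, and seeded synthetic-data generators that
    emulate every input with recorded ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
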