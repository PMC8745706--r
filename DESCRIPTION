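Package: dropcn
Title: Multiplexed Droplet Digital PCR Copy-Number and Mutation Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for amplitude-multiplexed droplet digital PCR
    (ddPCR) assays that measure gene copy number and point mutations from
    genomic or cell-free DNA. Covers droplet-level two-channel amplitude
    gating against control-derived thresholds, Poisson partitioning
    statistics for copies-per-microlitre quantification with confidence
    intervals, androgen receptor (AR) copy-number calling with
    X-hemizygosity correction, T877A mutant-fraction estimation, chromosome
    X copy number, amplification classification against a healthy-control
    threshold, and cohort-level association statistics (Fisher's exact,
    Mann-Whitney, Pearson). A synthetic droplet generator with known ground
    truth emulates QX200-style wells so every stage is testable without
    instrument data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
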