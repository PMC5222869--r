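Package: junctionAS
Title: Junction-Based Differential Alternative Splicing and Expression
    Analysis for Two-Condition RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects alternative splicing events (exon skipping,
    alternative 5'/3' splice sites, intron retention, mutually exclusive
    exons) from spliced read alignments of a control versus a stressed
    sample group.  Junction reads are filtered by anchor length and
    non-redundant support, exon clusters are reconstructed per gene,
    events are scored with two Fisher exact tests (junction counts and
    alternative-region coverage) whose P-values are combined by a
    weighted arithmetic mean and gated by Benjamini-Hochberg FDR.  Also
    provides RPKM quantification, threshold-based differential
    expression calling, direction-aware multi-group DEG overlap,
    Fisher/chi-squared term enrichment, a synthetic spliced-read
    simulator with planted effects for validation, and a small pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
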