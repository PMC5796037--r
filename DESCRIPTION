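Package: mirpair
Title: Integrated miRNA-mRNA Expression Analysis with Target-Site Consensus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multistep integrated analysis of miRNA and mRNA expression in
    tumor/normal cohorts: per-dataset differential expression by two-sample
    t-test and log2 fold-change thresholds, cross-dataset consensus calling,
    inverse Pearson correlation pairing on matched samples, a three-predictor
    miRNA target-site consensus (seed-match scanning, duplex minimum free
    energy, site accessibility), intersection with overexpression RNA-seq
    profiles to nominate candidate targets, hypergeometric gene-set
    enrichment, and delta-delta-Ct relative quantification. Ships a synthetic
    cohort generator with planted regulatory truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    fgsea,
    BiocGenerics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
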