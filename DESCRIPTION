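Package: lncnet
Title: Integrative lncRNA-mRNA Coexpression and Biomarker Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for integrative analysis of long noncoding RNA (lncRNA)
    and mRNA expression in small case-control cohorts: differential
    expression filtering on FPKM with fold-change and p-value thresholds,
    lncRNA cataloguing (length/location filters and a coding-potential
    consensus), Pearson coexpression networks clustered with a from-scratch
    Markov clustering (MCL) implementation, cis (genomic window) and trans
    (coexpression plus RNA-RNA duplex) target inference, hypergeometric
    gene-set enrichment with fold-enrichment scores, qRT-PCR 2^-ddCt
    quantification, and single/combined-marker ROC evaluation. Includes a
    synthetic-data generator that emulates the statistical structure such
    studies assume, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
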