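Package: rvburden
Title: Rare-Variant Collapsing Burden Analysis with Ancestry Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-based rare-variant collapsing association analysis for
    case-control cohorts: qualifying-variant models (ultrarare and
    frequency-bounded loss-of-function, synonymous negative control),
    ancestry clustering by principal components and Louvain community
    detection, exact stratified Cochran-Mantel-Haenszel and Fisher tests
    with Mantel-Haenszel pooled odds ratios, a gene-intolerance (LOEUF)
    threshold scan with permutation empirical p-values, gene-set
    enrichment batteries with false-discovery-rate control, and Poisson
    enrichment tests for trio de novo variants.  Includes a synthetic
    cohort generator that emulates the stratified case-control structure
    the methods assume, for calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    cluster,
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
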