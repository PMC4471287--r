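Package: convergeomics
Title: Multi-Omic Convergence Analysis for Perturbed Neural Stem Cell Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies whether the mRNA, microRNA and DNA-methylation changes of a
    perturbed (gene-knockdown) neural stem cell population overlap, agree in
    direction, and correlate with the changes seen in a reference cell-state
    contrast (differentiating versus proliferating controls). Provides exact
    hypergeometric overlap tests over an empirically detectable feature pool,
    directional fold-change concordance, NanoString nCounter style count
    normalization with negative-control detection thresholds, RRBS CpG-cluster
    calling (50 bp rule) with per-cluster t-tests and strand-aware gene
    mapping, and a deterministic synthetic multi-omics generator with planted
    shared-signal structure so every stage is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    IRanges,
    S4Vectors,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
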