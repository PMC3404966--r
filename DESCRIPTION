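Package: mirantag
Title: Antagonism Pattern Detection for MicroRNA Target Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers microRNA-target interactions from paired miRNA and mRNA
    expression profiles by detecting the "antagonism pattern": a triangular
    joint-expression shape in which simultaneously elevated miRNA and target
    expression is statistically under-represented. Provides the non-linear
    antagonism coefficient (a Kolmogorov-Smirnov-type sup statistic against a
    sample-shuffle null) with permutation p-values, a synthetic triangular-data
    simulator and power benchmark, a leave-one-out-corrected Pearson
    correlation baseline, bipartite network assembly with hub detection
    calibrated on randomized data, miRNA seed-match enrichment in 3'UTRs, and
    hypergeometric gene-set enrichment of predicted target sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    fgsea,
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
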