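Package: mirdegree
Title: Ranking Dysregulated miRNAs by the Network Centrality of Their Validated Targets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for ranking differentially expressed microRNAs by the
    functional importance of their experimentally validated protein targets.
    Builds protein-protein interaction (PPI) subnetworks from validated
    miRNA-target tables, computes degree, closeness and stress centralities,
    compares targeted networks against random-protein baselines (ANOVA and
    permutation tests), performs hypergeometric gene-set over-representation
    with Bonferroni correction, processes qPCR Ct plates into interplate-
    calibrated, global-mean-normalized 2^-ddCt fold changes with a concordant
    2-fold dysregulation filter, and scores each dysregulated miRNA by the
    summed PPI degree of its targets. A synthetic-data generator (scale-free
    graphs, hub-biased target assignment, two-condition duplicate qPCR plates
    with planted fold changes) exercises every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    fgsea,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
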