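Package: cernet
Title: Competing Endogenous RNA Network Inference and Single-Line
    Regulation Biomarker Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers lncRNA-miRNA-mRNA competing endogenous RNA (ceRNA)
    networks from miRNA-target pair lists using a hypergeometric
    shared-miRNA overlap test with Benjamini-Hochberg correction,
    extracts condition-specific subnetworks from two-group differential
    expression results, and scores each miRNA's single-line regulatory
    power (NSR-mRNA, NSR-lncRNA and their sum NSR-sponge) to prioritize
    candidate biomarker miRNAs by Wilcoxon signed-rank significance.
    Includes bipartite network utilities, topological characterization
    (LMC-miRNA classification, group partitions, distribution tests,
    rank-based ROC/AUC), and a synthetic-data generator with planted
    biomarker structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    limma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
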