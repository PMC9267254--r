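#' Run the full biomarker-discovery pipeline
#'
#' Differential expression on the miRNA and mRNA matrices, global
#' ceRNA network inference ([infer_triplets()]), condition-specific
#' extraction ([extract_condition_specific()]), NSR scoring and
#' candidate selection ([score_nsr()]). DE sets may be supplied
#' directly (e.g. from [read_de_table()]) to skip the built-in engine.
#'
#' @param ds a [simulate_dataset()] result, or any list with elements
#'   `mrna_net`, `lncrna_net`, `expr_mirna`, `expr_mrna`.
#' @param alpha_triplet adj.P threshold of the overlap test.
#' @param alpha_de,lfc_threshold DE screening thresholds.
#' @param alpha_nsr per-metric NSR significance threshold.
#' @param de_method engine for [differential_expression()].
#' @param nsr_method method for [nsr_significance()].
#' @param universe miRNA universe policy for [infer_triplets()].
#' @param de_mirnas,de_mrnas optional precomputed DE id sets
#'   (overriding the expression matrices).
#' @return list with `de_mirna`, `de_mrna` (DE tables or NULL),
#'   `de_mirna_ids`, `de_mrna_ids`, `global`, `specific`, `profiles`,
#'   `candidates` (character vector of candidate miRNA ids).
#' @export
run_pipeline <- function(ds, alpha_triplet = 0.01, alpha_de = 0.05,
                         lfc_threshold = 1, alpha_nsr = 0.05,
                         de_method = "welch", nsr_method = "signed_rank",
                         universe = "union",
                         de_mirnas = NULL, de_mrnas = NULL) {
  de_mir_tab <- de_mrna_tab <- NULL
  if (is.null(de_mirnas)) {
    de_mir_tab <- differential_expression(ds$expr_mirna, method = de_method,
                                          alpha_de = alpha_de,
                                          lfc_threshold = lfc_threshold)
    s <- de_sets(de_mir_tab, alpha_de, lfc_threshold)
    de_mirnas <- c(s$up, s$down)
  }
  if (is.null(de_mrnas)) {
    de_mrna_tab <- differential_expression(ds$expr_mrna, method = de_method,
                                           alpha_de = alpha_de,
                                           lfc_threshold = lfc_threshold)
    s <- de_sets(de_mrna_tab, alpha_de, lfc_threshold)
    de_mrnas <- c(s$up, s$down)
  }
  global <- infer_triplets(ds$mrna_net, ds$lncrna_net,
                           alpha = alpha_triplet, universe = universe)
  specific <- suppressWarnings(
    extract_condition_specific(global, de_mirnas, de_mrnas))
  profiles <- score_nsr(specific, alpha = alpha_nsr, method = nsr_method)
  list(de_mirna = de_mir_tab, de_mrna = de_mrna_tab,
       de_mirna_ids = sort(de_mirnas), de_mrna_ids = sort(de_mrnas),
       global = global, specific = specific, profiles = profiles,
       candidates = profiles$mirna[profiles$is_candidate])
}

#' Precision and recall of candidate recovery
#'
#' @param candidates predicted miRNA ids.
#' @param truth planted miRNA ids.
#' @return named numeric vector `precision`, `recall` (an empty
#'   prediction or truth set scores 1 on its own axis).
#' @export
recovery_stats <- function(candidates, truth) {
  tp <- length(intersect(candidates, truth))
  c(precision = if (length(candidates)) tp / length(candidates) else 1,
    recall = if (length(truth)) tp / length(truth) else 1)
}

#' Published prostate-cancer candidate miRNA table
#'
#' The curated reference table of 12 candidate biomarker miRNAs
#' reported for prostate cancer metastasis, with their published
#' differential-expression statistics, single-line regulation counts
#' (NSR-mRNA, NSR-lncRNA, NSR-sponge) with per-metric P-values, and
#' per-miRNA ROC AUCs. Shipped with the package as a worked reference
#' input for the model's definitional identities and for AUC
#' summaries.
#'
#' @return data.frame with columns `mirna`, `adj_p_value`, `log2_fc`,
#'   `nsr_mrna`, `p_mrna`, `nsr_lncrna`, `p_lncrna`, `nsr_sponge`,
#'   `p_sponge`, `auc`.
#' @export
published_candidates <- function() {
  path <- system.file("extdata", "pca_candidate_mirnas.tsv",
                      package = "cernet", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
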