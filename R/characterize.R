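#' Classify lncRNA/mRNA-competed (LMC) miRNAs
#'
#' A miRNA is LMC when it appears in both the miRNA-mRNA and the
#' miRNA-lncRNA networks, i.e. it can be competed for by both target
#' classes. Derived purely from network membership, never from
#' expression.
#'
#' @param mrna_net,lncrna_net `bipartite_network`s.
#' @return sorted character vector of LMC miRNA ids.
#' @export
classify_lmc <- function(mrna_net, lncrna_net) {
  sort(intersect(mrna_net$mirnas, lncrna_net$mirnas))
}

#' Partition miRNAs by single-line regulatory power
#'
#' Group I: no single-line regulation at all. Group II: single-line
#' regulation solely on mRNAs or solely on lncRNAs. Group III:
#' single-line regulation on both. The partition is exhaustive and
#' exclusive.
#'
#' @param profiles data.frame from [compute_nsr()].
#' @return data.frame `mirna`, `nsr_mrna`, `nsr_lncrna`, `group`
#'   (factor with levels I, II, III).
#' @export
assign_groups <- function(profiles) {
  both <- profiles$nsr_mrna > 0 & profiles$nsr_lncrna > 0
  none <- profiles$nsr_mrna == 0 & profiles$nsr_lncrna == 0
  grp <- ifelse(both, "III", ifelse(none, "I", "II"))
  data.frame(mirna = profiles$mirna,
             nsr_mrna = profiles$nsr_mrna,
             nsr_lncrna = profiles$nsr_lncrna,
             group = factor(grp, levels = c("I", "II", "III")),
             stringsAsFactors = FALSE)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' @param values_a,values_b non-empty numeric vectors.
#' @return list with `statistic` (D) and `p_value` (two-sided).
#' @export
compare_distributions <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) {
    stop("both samples must be non-empty")
  }
  ks <- suppressWarnings(stats::ks.test(values_a, values_b))
  list(statistic = unname(ks$statistic), p_value = ks$p.value)
}

#' Chi-squared test of biomarker proportions across groups
#'
#' Pearson chi-squared (no continuity correction) on the groups x
#' \{biomarker, non-biomarker\} contingency table, e.g. the Group
#' I/II/III biomarker fractions.
#'
#' @param counts data.frame or matrix with columns `biomarkers` and
#'   `total` (one row per group), all totals > 0, >= 2 groups.
#' @return list with `statistic` (chi-squared) and `p_value`.
#' @export
proportion_trend_test <- function(counts) {
  counts <- as.data.frame(counts)
  if (!all(c("biomarkers", "total") %in% names(counts))) {
    stop("`counts` needs columns biomarkers and total")
  }
  if (nrow(counts) < 2L) stop("need at least 2 groups")
  if (any(counts$total <= 0)) stop("every group must have total > 0")
  if (any(counts$biomarkers < 0 | counts$biomarkers > counts$total)) {
    stop("biomarkers must lie in [0, total]")
  }
  tab <- cbind(counts$biomarkers, counts$total - counts$biomarkers)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  stat <- unname(ct$statistic)
  if (is.nan(stat)) stat <- 0  # all-zero or all-full columns: no deviation
  list(statistic = stat, p_value = if (is.nan(ct$p.value)) 1 else ct$p.value)
}

#' Spearman rank correlation
#'
#' Tie-aware rank correlation, e.g. between the number of mRNA and
#' lncRNA targets per miRNA.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho` and `p_value`.
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Fraction of functional genes among class targets
#'
#' For each named class of miRNAs, the fraction of the class's target
#' union that falls in a functional gene set (TF, essential,
#' house-keeping, tumor-associated, ...). With
#' `denominator = "per_mirna_mean"` the per-miRNA fractions are
#' averaged instead.
#'
#' @param target_sets named list: miRNA id -> character vector of its
#'   targets.
#' @param gene_set character vector of gene symbols (or a list with a
#'   `members` element).
#' @param classes named list: class label -> miRNA ids. Defaults to a
#'   single class `all` holding every miRNA.
#' @param denominator `"union"` or `"per_mirna_mean"`.
#' @return named numeric vector of fractions (NA when a class has an
#'   empty target union).
#' @export
functional_fraction <- function(target_sets, gene_set, classes = NULL,
                                denominator = c("union", "per_mirna_mean")) {
  denominator <- match.arg(denominator)
  if (is.list(gene_set) && !is.null(gene_set$members)) {
    gene_set <- gene_set$members
  }
  if (is.null(classes)) classes <- list(all = names(target_sets))
  vapply(classes, function(members) {
    sets <- target_sets[intersect(members, names(target_sets))]
    if (denominator == "union") {
      u <- unique(unlist(sets, use.names = FALSE))
      if (!length(u)) return(NA_real_)
      mean(u %in% gene_set)
    } else {
      fr <- vapply(sets, function(s) {
        if (!length(s)) NA_real_ else mean(unique(s) %in% gene_set)
      }, numeric(1))
      if (all(is.na(fr))) NA_real_ else mean(fr, na.rm = TRUE)
    }
  }, numeric(1))
}

#' ROC AUC for one feature
#'
#' Area under the ROC curve computed as the Mann-Whitney concordance
#' probability between the case and reference groups, with ties
#' counting one half. With `orientation = "auto"` the reported AUC is
#' `max(a, 1 - a)` together with the implied direction (discriminative
#' ability is direction-symmetric); with `"fixed"` the direction
#' follows the sign of the feature's log2 fold change, so a marker
#' down-regulated in cases is scored as "low value predicts case".
#'
#' @param expr an [expression_matrix()].
#' @param feature feature id present in `expr`.
#' @param orientation `"auto"` or `"fixed"`.
#' @return list with `feature`, `auc` and `direction`
#'   (`"up_in_case"` or `"down_in_case"`).
#' @export
compute_auc <- function(expr, feature, orientation = c("auto", "fixed")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(expr, "expr_matrix"))
  if (!feature %in% rownames(expr$values)) stop("unknown feature: ", feature)
  g <- expr$groups
  ref <- expr$values[feature, g == levels(g)[1L]]
  case <- expr$values[feature, g == levels(g)[2L]]
  if (!length(ref) || !length(case)) stop("both groups must be non-empty")
  r <- rank(c(case, ref))
  nc <- length(case); nr <- length(ref)
  a <- (sum(r[seq_len(nc)]) - nc * (nc + 1) / 2) / (nc * nr)  # P(case > ref)
  if (orientation == "auto") {
    auc <- max(a, 1 - a)
    direction <- if (a >= 0.5) "up_in_case" else "down_in_case"
  } else {
    lfc <- mean(case) - mean(ref)
    direction <- if (lfc >= 0) "up_in_case" else "down_in_case"
    auc <- if (lfc >= 0) a else 1 - a
  }
  list(feature = feature, auc = auc, direction = direction)
}

#' Mean AUC over a set of markers
#'
#' @param results list of [compute_auc()] results, a data.frame with
#'   an `auc` column, or a bare numeric vector of AUCs.
#' @return arithmetic mean AUC.
#' @export
mean_auc <- function(results) {
  if (is.data.frame(results)) {
    auc <- results$auc
  } else if (is.list(results)) {
    auc <- vapply(results, function(r) r$auc, numeric(1))
  } else {
    auc <- as.numeric(results)
  }
  if (!length(auc)) stop("no AUC values")
  mean(auc)
}
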