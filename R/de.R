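#' Construct a labelled log2 expression matrix
#'
#' @param values numeric matrix, features in rows (rownames required),
#'   samples in columns (colnames required).
#' @param groups named character/factor vector mapping every sample to
#'   one of exactly two groups.
#' @param reference group label to use as the reference (e.g. primary
#'   tumour); log2 fold changes are case minus reference. Defaults to
#'   the first group label encountered.
#' @return an object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, groups, reference = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs feature rownames and sample colnames")
  }
  if (is.null(names(groups))) {
    if (length(groups) != ncol(values)) stop("unnamed groups of wrong length")
    names(groups) <- colnames(values)
  }
  miss <- setdiff(colnames(values), names(groups))
  if (length(miss)) stop("samples without a label: ", paste(miss, collapse = ", "))
  groups <- as.character(groups[colnames(values)])
  lev <- unique(groups)
  if (length(lev) != 2L) stop("exactly two groups required, got: ",
                              paste(lev, collapse = ", "))
  if (is.null(reference)) reference <- lev[1L]
  if (!reference %in% lev) stop("reference group not among labels")
  groups <- factor(groups, levels = c(reference, setdiff(lev, reference)))
  structure(list(values = values,
                 groups = stats::setNames(groups, colnames(values))),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  tab <- table(x$groups)
  cat(sprintf("expression matrix: %d features x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s n=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Two-group differential expression
#'
#' Per-feature two-sided test of the group mean difference on the log2
#' scale. `method = "welch"` runs an unequal-variance t-test per
#' feature; `method = "moderated"` fits the empirical-Bayes moderated
#' t (variance shrinkage toward a pooled prior) via limma. p-values
#' are BH-adjusted over all features. A feature that is constant in
#' both groups gets p = 1 under `welch` (flagged in `note`).
#'
#' @param expr an [expression_matrix()].
#' @param method `"welch"` or `"moderated"`.
#' @param alpha_de,lfc_threshold thresholds for the DE call
#'   (`adj_p_value < alpha_de` and `|log2_fc| > lfc_threshold`, both
#'   strict).
#' @return data.frame with `feature_id`, `log2_fc` (case minus
#'   reference), `p_value`, `adj_p_value`, `is_de`, `note`.
#' @export
differential_expression <- function(expr, method = c("welch", "moderated"),
                                    alpha_de = 0.05, lfc_threshold = 1) {
  method <- match.arg(method)
  stopifnot(inherits(expr, "expr_matrix"))
  g <- expr$groups
  if (any(table(g) < 2L)) stop("each group needs at least 2 samples")
  ref <- levels(g)[1L]
  case <- levels(g)[2L]
  vals <- expr$values
  lfc <- rowMeans(vals[, g == case, drop = FALSE]) -
    rowMeans(vals[, g == ref, drop = FALSE])
  note <- rep("", nrow(vals))
  if (method == "welch") {
    p <- vapply(seq_len(nrow(vals)), function(i) {
      tryCatch(stats::t.test(vals[i, g == case], vals[i, g == ref])$p.value,
               error = function(e) NA_real_)
    }, numeric(1))
    const <- is.na(p)
    p[const] <- 1
    note[const] <- "constant"
  } else {
    design <- stats::model.matrix(~g)
    fit <- limma::eBayes(limma::lmFit(vals, design))
    p <- fit$p.value[, 2L]
  }
  out <- data.frame(feature_id = rownames(vals),
                    log2_fc = unname(lfc),
                    p_value = unname(p),
                    adj_p_value = unname(bh_adjust(p)),
                    note = note,
                    stringsAsFactors = FALSE)
  out$is_de <- out$adj_p_value < alpha_de & abs(out$log2_fc) > lfc_threshold
  out[, c("feature_id", "log2_fc", "p_value", "adj_p_value", "is_de", "note")]
}

#' Split DE calls into up- and down-regulated sets
#'
#' Partition of the features passing `adj_p_value < alpha_de` and
#' `|log2_fc| > lfc_threshold` (strict, matching the screening rule)
#' by the sign of the fold change.
#'
#' @param results output of [differential_expression()] or
#'   [read_de_table()].
#' @param alpha_de,lfc_threshold thresholds.
#' @return list with character vectors `up` and `down`.
#' @export
de_sets <- function(results, alpha_de = 0.05, lfc_threshold = 1) {
  if (!nrow(results)) return(list(up = character(0), down = character(0)))
  de <- results$adj_p_value < alpha_de & abs(results$log2_fc) > lfc_threshold
  list(up = sort(results$feature_id[de & results$log2_fc > 0]),
       down = sort(results$feature_id[de & results$log2_fc < 0]))
}
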