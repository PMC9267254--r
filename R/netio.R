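#' Normalize miRNA identifiers
#'
#' Canonicalizes miRNA symbols to the `miR-`/`let-` convention and
#' optionally strips the species prefix (e.g. `hsa-`). Public databases
#' are inconsistent in both respects (`hsa-mir-21`, `MIR-21`,
#' `miR-21`), so pair lists from several sources must be brought to one
#' form before edges can be merged.
#'
#' @param ids character vector of miRNA symbols.
#' @param strip_prefix drop a leading three/four-letter species prefix
#'   (`hsa-`, `mmu-`, ...) when it precedes a `mir`/`let` stem.
#' @return character vector of normalized symbols.
#' @examples
#' normalize_mirna_id(c("hsa-miR-23b-3p", "hsa-mir-21", "hsa-let-7a"))
#' @export
normalize_mirna_id <- function(ids, strip_prefix = TRUE) {
  x <- trimws(as.character(ids))
  if (strip_prefix) {
    x <- sub("^[A-Za-z]{3,4}-(?=(mir|let))", "", x, perl = TRUE,
             ignore.case = TRUE)
  }
  x <- sub("^mir(?=[-0-9])", "miR", x, perl = TRUE, ignore.case = TRUE)
  x <- sub("^let(?=[-0-9])", "let", x, perl = TRUE, ignore.case = TRUE)
  x
}

#' Load a miRNA-target pair list
#'
#' Reads a tab-separated pair list (`regulator<TAB>target` with
#' optional `source` and `support` columns), normalizes miRNA symbols,
#' merges duplicate (regulator, target) rows (sources unioned, support
#' counts summed) and then drops pairs below `min_support`. Rows
#' without a support column count as one supporting experiment.
#'
#' @param path path to the TSV file (no header).
#' @param target_class `"mRNA"` or `"lncRNA"`; attached to every pair.
#' @param min_support minimum merged support count to keep a pair.
#' @param normalize normalize miRNA ids with [normalize_mirna_id()].
#' @param strip_prefix passed to [normalize_mirna_id()].
#' @return data.frame with columns `regulator`, `target`,
#'   `target_class`, `sources` (comma-collapsed set), `support`,
#'   sorted by (regulator, target).
#' @export
load_pairs <- function(path, target_class = c("mRNA", "lncRNA"),
                       min_support = 1, normalize = TRUE,
                       strip_prefix = TRUE) {
  target_class <- match.arg(target_class)
  if (!file.exists(path)) stop("pair file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) stop("empty pair file: ", path)
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- nf < 2L | nf > 4L
  if (any(bad)) {
    stop("malformed row (expected 2-4 tab-separated columns) at line ",
         idx[which(bad)[1L]], " of ", path)
  }
  reg <- trimws(vapply(fields, `[[`, "", 1L))
  tgt <- trimws(vapply(fields, `[[`, "", 2L))
  src <- vapply(fields, function(f) if (length(f) >= 3L) trimws(f[3L]) else NA_character_, "")
  sup_chr <- vapply(fields, function(f) if (length(f) >= 4L) trimws(f[4L]) else NA_character_, "")
  sup <- suppressWarnings(as.numeric(sup_chr))
  if (any(!is.na(sup_chr) & is.na(sup))) {
    stop("non-numeric support count at line ",
         idx[which(!is.na(sup_chr) & is.na(sup))[1L]], " of ", path)
  }
  sup[is.na(sup)] <- 1
  if (normalize) reg <- normalize_mirna_id(reg, strip_prefix = strip_prefix)
  if (any(!nzchar(reg)) || any(!nzchar(tgt))) {
    stop("empty regulator or target id after normalization in ", path)
  }
  key <- paste(reg, tgt, sep = "\r")
  support <- vapply(split(sup, key), sum, numeric(1))
  sources <- vapply(split(src, key), function(s) {
    s <- sort(unique(s[!is.na(s) & nzchar(s)]))
    if (length(s)) paste(s, collapse = ",") else NA_character_
  }, "")
  uk <- names(support)
  parts <- strsplit(uk, "\r", fixed = TRUE)
  out <- data.frame(
    regulator = vapply(parts, `[[`, "", 1L),
    target = vapply(parts, `[[`, "", 2L),
    target_class = target_class,
    sources = unname(sources),
    support = unname(support),
    stringsAsFactors = FALSE
  )
  out <- out[out$support >= min_support, , drop = FALSE]
  out <- out[order(out$regulator, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load named gene sets
#'
#' Each file holds either one symbol per line, or two tab-separated
#' columns `set-name<TAB>symbol`. One-column files are named after the
#' file (basename without extension). Duplicate symbols collapse.
#'
#' @param paths character vector of file paths.
#' @return named list of character vectors.
#' @export
load_gene_sets <- function(paths) {
  sets <- list()
  for (path in paths) {
    if (!file.exists(path)) stop("gene-set file not found: ", path)
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("empty gene-set file: ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (all(lengths(fields) >= 2L)) {
      nm <- vapply(fields, `[[`, "", 1L)
      sym <- vapply(fields, `[[`, "", 2L)
      for (s in unique(nm)) {
        sets[[s]] <- sort(unique(c(sets[[s]], sym[nm == s])))
      }
    } else {
      nm <- sub("\\.[^.]*$", "", basename(path))
      sets[[nm]] <- sort(unique(c(sets[[nm]], vapply(fields, `[[`, "", 1L))))
    }
  }
  sets
}

#' Write a result table deterministically
#'
#' Rows are sorted by the first column (then remaining columns) so
#' repeated runs produce byte-identical files.
#'
#' @param records a data.frame (zero rows allowed; the header is still
#'   written).
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_report <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(records)) records <- as.data.frame(records)
  if (nrow(records) > 1L) {
    ord <- do.call(order, unname(as.list(records)))
    records <- records[ord, , drop = FALSE]
  }
  rownames(records) <- NULL
  ok <- tryCatch({
    if (format == "tsv") {
      utils::write.table(records, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = TRUE)
    } else {
      jsonlite::write_json(records, path, dataframe = "rows",
                           digits = NA, na = "null")
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write report to ", path, ": ",
                        conditionMessage(ok))
  invisible(NULL)
}

#' Read back a report written by [write_report()]
#' @param path file path.
#' @param format `"tsv"` or `"json"`.
#' @return data.frame.
#' @export
read_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::read.delim(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}

#' Read a log2 expression matrix with group labels
#'
#' The expression TSV has a header row; the first column holds feature
#' ids, remaining columns one sample each. The label TSV has two
#' columns `sample<TAB>group` without a header.
#'
#' @param expr_path expression TSV.
#' @param label_path two-column sample-label TSV.
#' @param reference group label to treat as the reference; defaults to
#'   the first label encountered.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(expr_path, label_path, reference = NULL) {
  tab <- utils::read.delim(expr_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(values) <- as.character(tab[[1L]])
  lab <- utils::read.delim(label_path, header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(lab) < 2L) stop("label file must have two columns: ", label_path)
  groups <- stats::setNames(as.character(lab[[2L]]), as.character(lab[[1L]]))
  expression_matrix(values, groups, reference = reference)
}

#' Read a precomputed differential-expression table
#'
#' Columns: `feature`, `log2_fc`, `p_value`, `adj_p_value` (header
#' required, extra columns ignored). Useful when DE was produced by an
#' external engine.
#'
#' @param path TSV path.
#' @param alpha_de,lfc_threshold thresholds used to fill `is_de`.
#' @return data.frame shaped like [differential_expression()] output.
#' @export
read_de_table <- function(path, alpha_de = 0.05, lfc_threshold = 1) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("feature", "log2_fc", "p_value", "adj_p_value")
  if (!all(need %in% names(tab))) {
    stop("DE table must have columns: ", paste(need, collapse = ", "))
  }
  tab <- tab[, need]
  names(tab)[1L] <- "feature_id"
  tab$is_de <- tab$adj_p_value < alpha_de & abs(tab$log2_fc) > lfc_threshold
  tab
}
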