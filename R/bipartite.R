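#' Build a bipartite miRNA-target network
#'
#' The substrate of all downstream scoring: a set of (miRNA, target)
#' edges of a single target class (mRNA or lncRNA). Duplicate edges
#' collapse; node sets are exactly the edge endpoints.
#'
#' @param pairs data.frame with columns `regulator`/`mirna` and
#'   `target` (e.g. from [load_pairs()]); an optional `target_class`
#'   column must be constant.
#' @param target_class `"mRNA"` or `"lncRNA"`; required if `pairs` has
#'   no `target_class` column.
#' @return an object of class `bipartite_network` with elements
#'   `edges` (data.frame `mirna`, `target`), `mirnas`, `targets`,
#'   `target_class`.
#' @export
build_network <- function(pairs, target_class = NULL) {
  if (!is.data.frame(pairs)) stop("`pairs` must be a data.frame")
  reg_col <- intersect(c("regulator", "mirna"), names(pairs))[1L]
  if (is.na(reg_col) || !"target" %in% names(pairs)) {
    stop("`pairs` needs a regulator/mirna column and a target column")
  }
  if ("target_class" %in% names(pairs) && nrow(pairs)) {
    cls <- unique(as.character(pairs$target_class))
    if (length(cls) > 1L) {
      stop("mixed target_class in pair list: ", paste(cls, collapse = ", "))
    }
    if (is.null(target_class)) target_class <- cls
    if (target_class != cls) stop("target_class mismatch with pair list")
  }
  if (is.null(target_class)) stop("target_class must be given")
  target_class <- match.arg(target_class, c("mRNA", "lncRNA"))
  edges <- unique(data.frame(mirna = as.character(pairs[[reg_col]]),
                             target = as.character(pairs$target),
                             stringsAsFactors = FALSE))
  edges <- edges[order(edges$mirna, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 mirnas = sort(unique(edges$mirna)),
                 targets = sort(unique(edges$target)),
                 target_class = target_class),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("bipartite miRNA-%s network: %d miRNAs, %d targets, %d edges\n",
              x$target_class, length(x$mirnas), length(x$targets),
              nrow(x$edges)))
  invisible(x)
}

#' Degree of a node in a bipartite network
#'
#' @param net a `bipartite_network`.
#' @param node node id.
#' @param side `"miRNA"` or `"target"` -- the side the node lives on.
#' @return integer count of incident edges.
#' @export
node_degree <- function(net, node, side = c("miRNA", "target")) {
  side <- match.arg(side)
  if (side == "miRNA") {
    if (!node %in% net$mirnas) stop("unknown miRNA: ", node)
    sum(net$edges$mirna == node)
  } else {
    if (!node %in% net$targets) stop("unknown target: ", node)
    sum(net$edges$target == node)
  }
}

#' Single-line targets of a miRNA
#'
#' A target is a single-line (degree-1) regulation of `mirna` when the
#' edge (mirna, target) exists and no other miRNA in *this* network
#' targets it. Single-line regulations are the structurally vulnerable
#' sites the NSR statistics count, so which network the operator is
#' applied to (global reference vs condition-specific) matters and is
#' the caller's choice.
#'
#' @param net a `bipartite_network`.
#' @param mirna miRNA id present in `net`.
#' @return character vector of target ids (possibly empty), sorted.
#' @export
single_line_targets <- function(net, mirna) {
  if (!mirna %in% net$mirnas) stop("unknown miRNA: ", mirna)
  tdeg <- table(net$edges$target)
  mine <- net$edges$target[net$edges$mirna == mirna]
  sort(mine[tdeg[mine] == 1L])
}

#' Single-line regulation counts for every miRNA
#'
#' Vectorized form of [single_line_targets()]: the per-miRNA count of
#' targets whose only regulator is that miRNA.
#'
#' @param net a `bipartite_network`.
#' @return named integer vector over `net$mirnas`.
#' @export
single_line_counts <- function(net) {
  counts <- stats::setNames(integer(length(net$mirnas)), net$mirnas)
  if (!nrow(net$edges)) return(counts)
  tdeg <- table(net$edges$target)
  solo <- net$edges[tdeg[net$edges$target] == 1L, , drop = FALSE]
  if (nrow(solo)) {
    tab <- table(solo$mirna)
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Restrict a bipartite network to kept nodes
#'
#' Keeps exactly the edges with both endpoints in the keep sets and
#' recomputes the node sets from the surviving edges; nodes losing all
#' edges are dropped so degree statistics are not diluted by phantom
#' nodes. Restriction is idempotent.
#'
#' @param net a `bipartite_network`.
#' @param keep_mirnas,keep_targets character vectors of node ids.
#' @return a `bipartite_network` (possibly empty).
#' @export
restrict_network <- function(net, keep_mirnas, keep_targets) {
  keep <- net$edges$mirna %in% keep_mirnas & net$edges$target %in% keep_targets
  build_network(data.frame(regulator = net$edges$mirna[keep],
                           target = net$edges$target[keep],
                           stringsAsFactors = FALSE),
                target_class = net$target_class)
}
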