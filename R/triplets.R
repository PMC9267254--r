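#' Upper-tail hypergeometric probability
#'
#' P\[X >= k\] for X hypergeometric with population size `N`, `K`
#' successes and `n` draws: the probability that a lncRNA targeted by
#' `K` of the `N` miRNAs and an mRNA targeted by `n` of them share at
#' least `k` regulators by chance. Exact (no continuity
#' approximation).
#'
#' @param k observed shared count (>= 0).
#' @param K miRNAs targeting the lncRNA.
#' @param n miRNAs targeting the mRNA.
#' @param N miRNA universe size.
#' @return probability in (0, 1\]; vectorized over its arguments.
#' @examples
#' hypergeom_upper_tail(3, 4, 5, 10)  # 66/252
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  m <- max(length(k), length(K), length(n), length(N))
  k <- rep_len(k, m); K <- rep_len(K, m)
  n <- rep_len(n, m); N <- rep_len(N, m)
  if (any(k < 0 | K < 0 | n < 0 | N < 1 | K > N | n > N | k > pmin(K, n))) {
    stop("hypergeometric bounds violated: need 0 <= k <= min(K, n), K <= N, n <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with enforced
#' monotonicity; output order matches input order.
#'
#' @param p_values probabilities in (0, 1\].
#' @return adjusted probabilities, elementwise >= the raw values.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Infer the global lncRNA-miRNA-mRNA ceRNA network
#'
#' Tests every (lncRNA, mRNA) pair that shares at least one miRNA for
#' significant shared-miRNA overlap ([hypergeom_upper_tail()]),
#' BH-adjusts over exactly that family, and emits one triplet
#' (lncRNA, miRNA, mRNA) per shared miRNA of each pair with
#' adj.P below `alpha`. Pairs sharing no miRNA are never tested (they
#' cannot form triplets and would only dilute the FDR family).
#'
#' The miRNA universe N defaults to the union of the two networks'
#' miRNA sets; with `universe = "intersection"` the per-target counts
#' K and n are also restricted to the shared miRNAs so the
#' hypergeometric bounds stay valid.
#'
#' @param mrna_net,lncrna_net `bipartite_network`s of class mRNA and
#'   lncRNA respectively.
#' @param alpha significance threshold on the adjusted p-value
#'   (strict `<`).
#' @param universe `"union"`, `"intersection"` or `"fixed"`.
#' @param universe_size population size when `universe = "fixed"`.
#' @return an object of class `cerna_network` with elements
#'   `triplets` (data.frame `lncrna`, `mirna`, `mrna`), `pairs` (all
#'   tested pairs with `K`, `n`, `k`, `N`, `p_value`, `adj_p_value`,
#'   `significant`), node sets `mirnas`/`lncrnas`/`mrnas`, and
#'   `alpha`.
#' @export
infer_triplets <- function(mrna_net, lncrna_net, alpha = 0.01,
                           universe = c("union", "intersection", "fixed"),
                           universe_size = NULL) {
  universe <- match.arg(universe)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  all_mirnas <- union(mrna_net$mirnas, lncrna_net$mirnas)
  if (!length(all_mirnas)) stop("empty miRNA universe")
  common <- intersect(mrna_net$mirnas, lncrna_net$mirnas)
  N <- switch(universe,
              union = length(all_mirnas),
              intersection = length(common),
              fixed = {
                if (is.null(universe_size)) stop("universe_size required")
                as.integer(universe_size)
              })
  empty <- function() {
    new_cerna_network(
      triplets = data.frame(lncrna = character(0), mirna = character(0),
                            mrna = character(0), stringsAsFactors = FALSE),
      pairs = empty_pair_table(), alpha = alpha)
  }
  if (!length(common)) return(empty())

  medges <- mrna_net$edges[mrna_net$edges$mirna %in% common, , drop = FALSE]
  ledges <- lncrna_net$edges[lncrna_net$edges$mirna %in% common, , drop = FALSE]
  if (!nrow(medges) || !nrow(ledges)) return(empty())
  mrnas <- sort(unique(medges$target))
  lncrnas <- sort(unique(ledges$target))
  Minc <- Matrix::sparseMatrix(
    i = match(medges$mirna, common), j = match(medges$target, mrnas),
    x = 1, dims = c(length(common), length(mrnas)))
  Linc <- Matrix::sparseMatrix(
    i = match(ledges$mirna, common), j = match(ledges$target, lncrnas),
    x = 1, dims = c(length(common), length(lncrnas)))
  shared <- Matrix::crossprod(Linc, Minc)  # lncRNA x mRNA shared-miRNA counts
  nz <- Matrix::summary(shared)
  if (!nrow(nz)) return(empty())

  if (universe == "intersection") {
    Kdeg <- stats::setNames(Matrix::colSums(Linc), lncrnas)
    ndeg <- stats::setNames(Matrix::colSums(Minc), mrnas)
  } else {
    Kdeg <- table(lncrna_net$edges$target)
    ndeg <- table(mrna_net$edges$target)
  }
  pairs <- data.frame(
    lncrna = lncrnas[nz$i], mrna = mrnas[nz$j],
    K = as.integer(Kdeg[lncrnas[nz$i]]),
    n = as.integer(ndeg[mrnas[nz$j]]),
    k = as.integer(nz$x), N = N, stringsAsFactors = FALSE)
  pairs$p_value <- hypergeom_upper_tail(pairs$k, pairs$K, pairs$n, pairs$N)
  pairs$adj_p_value <- bh_adjust(pairs$p_value)
  pairs$significant <- pairs$adj_p_value < alpha
  pairs <- pairs[order(pairs$lncrna, pairs$mrna), , drop = FALSE]
  rownames(pairs) <- NULL

  sig <- pairs[pairs$significant, , drop = FALSE]
  if (nrow(sig)) {
    by_lnc <- split(ledges$mirna, ledges$target)
    by_mrna <- split(medges$mirna, medges$target)
    shared_list <- mapply(function(l, g) sort(intersect(by_lnc[[l]], by_mrna[[g]])),
                          sig$lncrna, sig$mrna, SIMPLIFY = FALSE)
    reps <- lengths(shared_list)
    triplets <- data.frame(lncrna = rep(sig$lncrna, reps),
                           mirna = unlist(shared_list, use.names = FALSE),
                           mrna = rep(sig$mrna, reps),
                           stringsAsFactors = FALSE)
  } else {
    triplets <- data.frame(lncrna = character(0), mirna = character(0),
                           mrna = character(0), stringsAsFactors = FALSE)
  }
  new_cerna_network(triplets = triplets, pairs = pairs, alpha = alpha)
}

empty_pair_table <- function() {
  data.frame(lncrna = character(0), mrna = character(0),
             K = integer(0), n = integer(0), k = integer(0), N = integer(0),
             p_value = numeric(0), adj_p_value = numeric(0),
             significant = logical(0), stringsAsFactors = FALSE)
}

new_cerna_network <- function(triplets, pairs, alpha) {
  triplets <- triplets[order(triplets$lncrna, triplets$mirna, triplets$mrna),
                       , drop = FALSE]
  rownames(triplets) <- NULL
  structure(list(triplets = triplets,
                 pairs = pairs,
                 mirnas = sort(unique(triplets$mirna)),
                 lncrnas = sort(unique(triplets$lncrna)),
                 mrnas = sort(unique(triplets$mrna)),
                 alpha = alpha),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cat(sprintf(paste0("ceRNA network: %d triplets among %d miRNAs, ",
                     "%d lncRNAs, %d mRNAs (%d/%d significant pairs, ",
                     "adj.P < %g)\n"),
              nrow(x$triplets), length(x$mirnas), length(x$lncrnas),
              length(x$mrnas), sum(x$pairs$significant), nrow(x$pairs),
              x$alpha))
  invisible(x)
}
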