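# Independent brute-force oracles used across the suite. These stay
# deliberately naive (full scans, closed-form sums) so they cannot
# share a code path with the implementation they check.

# upper-tail hypergeometric by direct combinatorial summation
hyper_enum <- function(k, K, n, N) {
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(choose(K, k:hi) * choose(N - K, n - (k:hi))) / choose(N, n)
}

# per-miRNA single-line counts by scanning the full edge list
brute_single_line <- function(edges, mirnas) {
  out <- stats::setNames(integer(length(mirnas)), mirnas)
  for (m in mirnas) {
    cnt <- 0L
    for (t in edges$target[edges$mirna == m]) {
      if (sum(edges$target == t) == 1L) cnt <- cnt + 1L
    }
    out[m] <- cnt
  }
  out
}

# AUC by counting concordant case/reference pairs, ties one half
brute_auc <- function(case, ref) {
  s <- 0
  for (x in case) for (y in ref) {
    s <- s + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  s / (length(case) * length(ref))
}

# random bipartite pair list
random_pairs <- function(n_mir, n_tgt, p) {
  mir <- sprintf("m%02d", seq_len(n_mir))
  tgt <- sprintf("t%02d", seq_len(n_tgt))
  hit <- which(stats::runif(n_mir * n_tgt) < p)
  idx <- arrayInd(hit, c(n_mir, n_tgt))
  data.frame(regulator = mir[idx[, 1]], target = tgt[idx[, 2]],
             stringsAsFactors = FALSE)
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# scaled-down generator settings for fast unit tests
small_config <- function(seed = 1, ...) {
  simulation_config(n_mirnas = 25, n_mrnas = 120, n_lncrnas = 60,
                    n_planted = 3, planted_single_line_mrna = 4,
                    planted_single_line_lncrna = 4, n_hub_mirnas = 8,
                    n_decoy_mirnas = 6, n_decoy_mrnas = 15,
                    n_samples = 10, seed = seed, ...)
}
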