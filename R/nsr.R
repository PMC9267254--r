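#' Extract the condition-specific ceRNA network
#'
#' Keeps exactly the triplets whose miRNA is differentially expressed
#' and whose mRNA is differentially expressed; the surviving lncRNAs
#' are the "functional" lncRNAs inferred by the model (they are not
#' filtered on expression). Pair results are restricted to pairs with
#' at least one surviving triplet; node sets are recomputed.
#'
#' @param global_net a `cerna_network` (the global reference).
#' @param de_mirnas,de_mrnas character vectors of DE feature ids.
#' @return a `cerna_network`; empty is valid (with a warning).
#' @export
extract_condition_specific <- function(global_net, de_mirnas, de_mrnas) {
  stopifnot(inherits(global_net, "cerna_network"))
  tr <- global_net$triplets
  keep <- tr$mirna %in% de_mirnas & tr$mrna %in% de_mrnas
  tr <- tr[keep, , drop = FALSE]
  if (!nrow(tr)) {
    warning("condition-specific network is empty: no triplet has both a ",
            "DE miRNA and a DE mRNA")
  }
  pairkey <- paste(global_net$pairs$lncrna, global_net$pairs$mrna, sep = "\r")
  livekey <- unique(paste(tr$lncrna, tr$mrna, sep = "\r"))
  pairs <- global_net$pairs[pairkey %in% livekey, , drop = FALSE]
  rownames(pairs) <- NULL
  new_cerna_network(triplets = tr, pairs = pairs, alpha = global_net$alpha)
}

#' Compute per-miRNA single-line regulation counts
#'
#' Projects the triplet set onto its two bipartite networks (the
#' deduplicated miRNA-mRNA and miRNA-lncRNA edge sets) and counts, for
#' every miRNA, the targets whose only regulator it is: `nsr_mrna`,
#' `nsr_lncrna`, and their sum `nsr_sponge` (the miRNA's single-line
#' sponges).
#'
#' @param specific_net a non-empty `cerna_network`, normally the
#'   condition-specific network from [extract_condition_specific()].
#' @return data.frame with one row per miRNA: `mirna`, `nsr_mrna`,
#'   `nsr_lncrna`, `nsr_sponge`.
#' @export
compute_nsr <- function(specific_net) {
  stopifnot(inherits(specific_net, "cerna_network"))
  tr <- specific_net$triplets
  if (!nrow(tr)) stop("cannot compute NSR on an empty ceRNA network")
  mnet <- build_network(unique(data.frame(regulator = tr$mirna,
                                          target = tr$mrna,
                                          stringsAsFactors = FALSE)),
                        target_class = "mRNA")
  lnet <- build_network(unique(data.frame(regulator = tr$mirna,
                                          target = tr$lncrna,
                                          stringsAsFactors = FALSE)),
                        target_class = "lncRNA")
  mirnas <- specific_net$mirnas
  nm <- single_line_counts(mnet)[mirnas]
  nl <- single_line_counts(lnet)[mirnas]
  data.frame(mirna = mirnas,
             nsr_mrna = as.integer(nm),
             nsr_lncrna = as.integer(nl),
             nsr_sponge = as.integer(nm + nl),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build an NSR profile from known single-line counts
#'
#' Applies the definitional identity NSR-sponge = NSR-mRNA +
#' NSR-lncRNA to given counts, e.g. when re-deriving the sponge column
#' of a published candidate table.
#'
#' @param mirna miRNA ids.
#' @param nsr_mrna,nsr_lncrna non-negative integer counts.
#' @return data.frame shaped like [compute_nsr()] output.
#' @export
nsr_profile <- function(mirna, nsr_mrna, nsr_lncrna) {
  if (any(nsr_mrna < 0) || any(nsr_lncrna < 0)) {
    stop("NSR counts must be non-negative")
  }
  data.frame(mirna = as.character(mirna),
             nsr_mrna = as.integer(nsr_mrna),
             nsr_lncrna = as.integer(nsr_lncrna),
             nsr_sponge = as.integer(nsr_mrna) + as.integer(nsr_lncrna),
             stringsAsFactors = FALSE)
}

#' Per-miRNA NSR significance
#'
#' One-sided probability that a miRNA's NSR value is high relative to
#' the network background. With `method = "signed_rank"` (default),
#' the miRNA's count is paired against every other miRNA's count, zero
#' differences are dropped, and the upper-tail Wilcoxon signed-rank
#' p-value is computed ([signed_rank_upper_p()]; exact for up to 25
#' nonzero differences, tie-corrected normal above). With
#' `method = "empirical"` the transparent upper-tail rank probability
#' `(1 + #\{other miRNAs with NSR >= this one\}) / n` is used instead;
#' the two methods order miRNAs identically.
#'
#' @param profiles data.frame from [compute_nsr()] (>= 3 rows).
#' @param metric `"mrna"`, `"lncrna"` or `"sponge"`.
#' @param method `"signed_rank"` or `"empirical"`.
#' @return `profiles` with the column `p_<metric>` filled.
#' @export
nsr_significance <- function(profiles,
                             metric = c("mrna", "lncrna", "sponge"),
                             method = c("signed_rank", "empirical")) {
  metric <- match.arg(metric)
  method <- match.arg(method)
  if (nrow(profiles) < 3L) stop("need at least 3 miRNA profiles")
  v <- profiles[[paste0("nsr_", metric)]]
  n <- length(v)
  if (length(unique(v)) == 1L) {
    warning("all NSR-", metric, " values identical; no signal (p = 1)")
    p <- rep(1, n)
  } else if (method == "signed_rank") {
    p <- vapply(seq_len(n), function(i) signed_rank_upper_p(v[i] - v[-i]),
                numeric(1))
  } else {
    p <- vapply(seq_len(n), function(i) (1 + sum(v[-i] >= v[i])) / n,
                numeric(1))
  }
  profiles[[paste0("p_", metric)]] <- p
  profiles
}

#' Call candidate biomarker miRNAs
#'
#' A miRNA is a candidate when all three of its NSR significance
#' probabilities (mRNA, lncRNA, sponge) fall below `alpha` -- no
#' multiplicity correction is applied across metrics or miRNAs at this
#' step; the filter is a raw per-metric threshold.
#'
#' @param profiles data.frame with `p_mrna`, `p_lncrna`, `p_sponge`
#'   filled (see [nsr_significance()]).
#' @param alpha per-metric significance threshold (strict `<`).
#' @return `profiles` with `is_candidate` set, sorted by `nsr_sponge`
#'   descending (ties broken by miRNA id).
#' @export
select_candidates <- function(profiles, alpha = 0.05) {
  if (!nrow(profiles)) {
    profiles$is_candidate <- logical(0)
    return(profiles)
  }
  need <- c("p_mrna", "p_lncrna", "p_sponge")
  if (!all(need %in% names(profiles)) ||
      any(is.na(unlist(profiles[need])))) {
    stop("significance columns p_mrna, p_lncrna, p_sponge must be filled")
  }
  profiles$is_candidate <- profiles$p_mrna < alpha &
    profiles$p_lncrna < alpha & profiles$p_sponge < alpha
  profiles <- profiles[order(-profiles$nsr_sponge, profiles$mirna), ,
                       drop = FALSE]
  rownames(profiles) <- NULL
  profiles
}

#' Score and select in one step
#'
#' Convenience wrapper: [compute_nsr()], [nsr_significance()] for all
#' three metrics, then [select_candidates()]. An empty network yields
#' an empty profile table instead of an error.
#'
#' @param specific_net a `cerna_network`.
#' @param alpha per-metric significance threshold.
#' @param method significance method, see [nsr_significance()].
#' @return profile data.frame with counts, p-values and
#'   `is_candidate`.
#' @export
score_nsr <- function(specific_net, alpha = 0.05,
                      method = c("signed_rank", "empirical")) {
  method <- match.arg(method)
  if (!nrow(specific_net$triplets)) {
    return(data.frame(mirna = character(0), nsr_mrna = integer(0),
                      nsr_lncrna = integer(0), nsr_sponge = integer(0),
                      p_mrna = numeric(0), p_lncrna = numeric(0),
                      p_sponge = numeric(0), is_candidate = logical(0),
                      stringsAsFactors = FALSE))
  }
  profiles <- compute_nsr(specific_net)
  if (nrow(profiles) < 3L) {
    warning("fewer than 3 miRNAs in the network; significance undefined, ",
            "p set to 1")
    profiles$p_mrna <- profiles$p_lncrna <- profiles$p_sponge <- 1
  } else {
    for (metric in c("mrna", "lncrna", "sponge")) {
      profiles <- suppressWarnings(
        nsr_significance(profiles, metric, method))
    }
  }
  select_candidates(profiles, alpha = alpha)
}
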