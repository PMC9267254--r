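triplet_net <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  tr <- data.frame(lncrna = m[, 1], mirna = m[, 2], mrna = m[, 3],
                   stringsAsFactors = FALSE)
  cernet:::new_cerna_network(tr, cernet:::empty_pair_table(), alpha = 0.01)
}

test_that("exact signed-rank p enumerates sign assignments under ties", {
  # four tied positive differences: only the all-positive assignment
  # reaches the observed rank sum, 1 of 2^4
  expect_equal(signed_rank_upper_p(c(4, 4, 4, 4)), 1 / 16)
  expect_equal(signed_rank_upper_p(c(1, 2, 3)), 1 / 8)
  expect_equal(signed_rank_upper_p(numeric(0)), 1)
  expect_equal(signed_rank_upper_p(c(0, 0)), 1)  # zeros dropped
  expect_equal(signed_rank_upper_p(c(-1, -2)), 1)  # all-negative: sure event
})

test_that("exact signed-rank p matches the psignrank distribution without ties", {
  set.seed(33)
  for (rep in 1:50) {
    n <- sample(3:15, 1)
    d <- sample(1:60, n) * sample(c(-1, 1), n, replace = TRUE)
    W <- sum(rank(abs(d))[d > 0])
    expect_equal(signed_rank_upper_p(d),
                 1 - stats::psignrank(W - 1, n), tolerance = 1e-12)
  }
})

test_that("large-sample signed-rank p matches the corrected normal approximation", {
  set.seed(44)
  d <- rnorm(40)
  ref <- suppressWarnings(stats::wilcox.test(d, alternative = "greater",
                                             exact = FALSE,
                                             correct = TRUE))$p.value
  expect_equal(signed_rank_upper_p(d), ref, tolerance = 1e-10)
})

test_that("NSR counts follow from the triplet projections", {
  # two lncRNAs competing through one miRNA for one mRNA
  net <- triplet_net("L1", "A", "G1", "L2", "A", "G1")
  prof <- compute_nsr(net)
  expect_equal(prof$nsr_mrna, 1L)
  expect_equal(prof$nsr_lncrna, 2L)
  expect_equal(prof$nsr_sponge, 3L)
  # shared lncRNA and mRNA: nothing is single-line
  net2 <- triplet_net("L1", "A", "G1", "L1", "B", "G1")
  prof2 <- compute_nsr(net2)
  expect_equal(prof2$nsr_sponge, c(0L, 0L))
  expect_error(compute_nsr(
    cernet:::new_cerna_network(net$triplets[0, ],
                               cernet:::empty_pair_table(), 0.01)), "empty")
})

test_that("NSR matches a brute-force degree scan on random networks", {
  set.seed(55)
  for (rep in 1:25) {
    nm <- sample(2:6, 1)
    tr <- unique(data.frame(
      lncrna = sprintf("L%d", sample(1:8, 20, TRUE)),
      mirna = sprintf("m%d", sample(seq_len(nm), 20, TRUE)),
      mrna = sprintf("G%d", sample(1:8, 20, TRUE)),
      stringsAsFactors = FALSE))
    net <- cernet:::new_cerna_network(tr, cernet:::empty_pair_table(), 0.01)
    prof <- compute_nsr(net)
    medges <- unique(tr[, c("mirna", "mrna")]); names(medges)[2] <- "target"
    ledges <- unique(tr[, c("mirna", "lncrna")]); names(ledges)[2] <- "target"
    expect_equal(stats::setNames(prof$nsr_mrna, prof$mirna),
                 brute_single_line(medges, prof$mirna))
    expect_equal(stats::setNames(prof$nsr_lncrna, prof$mirna),
                 brute_single_line(ledges, prof$mirna))
    expect_equal(prof$nsr_sponge, prof$nsr_mrna + prof$nsr_lncrna)
  }
})

test_that("condition-specific extraction filters triplets by DE membership", {
  net <- triplet_net("L1", "A", "G1", "L1", "B", "G2")
  kept <- suppressWarnings(extract_condition_specific(net, "A", "G1"))
  expect_equal(nrow(kept$triplets), 1L)
  expect_equal(kept$triplets$mirna, "A")
  expect_warning(extract_condition_specific(net, character(0), character(0)),
                 "empty")
  all_kept <- extract_condition_specific(net, c("A", "B"), c("G1", "G2"))
  expect_equal(all_kept$triplets, net$triplets)
})

test_that("significance ranks a dominant miRNA and degenerate profiles correctly", {
  prof <- nsr_profile(sprintf("m%d", 1:5), c(5, 1, 1, 1, 1), rep(0, 5))
  out <- nsr_significance(prof, "mrna", "signed_rank")
  expect_equal(out$p_mrna[1], 1 / 16)        # 4 positive differences
  expect_true(all(out$p_mrna[-1] >= 0.5))    # low scorers cannot be high
  emp <- nsr_significance(prof, "mrna", "empirical")
  expect_equal(emp$p_mrna[1], 1 / 5)
  expect_true(all(emp$p_mrna[-1] >= 0.5))
  expect_warning(out2 <- nsr_significance(nsr_profile(letters[1:4], rep(3, 4),
                                                      rep(0, 4)),
                                          "mrna"), "identical")
  expect_equal(out2$p_mrna, rep(1, 4))
  expect_error(nsr_significance(prof[1:2, ], "mrna"), "at least 3")
})

test_that("the two significance methods agree on candidate ordering", {
  prof <- nsr_profile(sprintf("m%d", 1:8), c(12, 9, 7, 5, 4, 2, 1, 0),
                      rep(0, 8))
  sr <- nsr_significance(prof, "mrna", "signed_rank")$p_mrna
  em <- nsr_significance(prof, "mrna", "empirical")$p_mrna
  expect_equal(cor(rank(sr), rank(em)), 1)
})

test_that("candidate selection is a strict three-way conjunction", {
  prof <- nsr_profile(c("a", "b", "c"), c(5, 4, 0), c(3, 2, 0))
  prof$p_mrna <- c(0.01, 0.01, 0.9)
  prof$p_lncrna <- c(0.04, 0.06, 0.9)
  prof$p_sponge <- c(0.02, 0.02, 0.9)
  out <- select_candidates(prof, alpha = 0.05)
  expect_equal(out$mirna[out$is_candidate], "a")  # b fails on p_lncrna
  expect_equal(out$mirna, c("a", "b", "c"))       # sorted by nsr_sponge desc
  expect_equal(nrow(select_candidates(prof[0, ])), 0L)
  prof$p_sponge <- NA_real_
  expect_error(select_candidates(prof), "filled")
})

test_that("projection sums equal the count of degree-1 targets", {
  ds <- simulate_dataset(small_config(seed = 8))
  res <- run_pipeline(ds)
  prof <- res$profiles
  tr <- res$specific$triplets
  mdeg <- table(unique(tr[, c("mirna", "mrna")])$mrna)
  ldeg <- table(unique(tr[, c("mirna", "lncrna")])$lncrna)
  expect_equal(sum(prof$nsr_mrna), sum(mdeg == 1L))
  expect_equal(sum(prof$nsr_lncrna), sum(ldeg == 1L))
  expect_equal(prof$nsr_sponge, prof$nsr_mrna + prof$nsr_lncrna)
})
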