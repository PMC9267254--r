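net_of <- function(mirnas, class) {
  build_network(data.frame(regulator = mirnas,
                           target = paste0("t_", seq_along(mirnas)),
                           stringsAsFactors = FALSE), class)
}

test_that("LMC classification is the symmetric miRNA-set intersection", {
  a <- net_of(c("A", "B"), "mRNA")
  b <- net_of(c("B", "C"), "lncRNA")
  expect_equal(classify_lmc(a, b), "B")
  expect_equal(classify_lmc(net_of("A", "mRNA"), net_of("B", "lncRNA")),
               character(0))
  same <- classify_lmc(net_of(c("A", "B"), "mRNA"), net_of(c("B", "A"), "lncRNA"))
  expect_equal(same, c("A", "B"))
  expect_equal(classify_lmc(a, b),
               sort(intersect(b$mirnas, a$mirnas)))  # symmetric
})

test_that("group assignment partitions miRNAs by single-line power", {
  prof <- nsr_profile(c("a", "b", "c", "d"), c(0, 3, 0, 1), c(0, 0, 2, 1))
  grp <- assign_groups(prof)
  expect_equal(as.character(grp$group), c("I", "II", "II", "III"))
  allz <- assign_groups(nsr_profile(c("x", "y", "z"), rep(0, 3), rep(0, 3)))
  expect_true(all(allz$group == "I"))
  expect_equal(sum(table(grp$group)), nrow(grp))  # exhaustive and exclusive
})

test_that("KS comparison handles identical, disjoint and null samples", {
  same <- compare_distributions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  apart <- compare_distributions(c(0, 0, 0), c(1, 1, 1))
  expect_equal(apart$statistic, 1)
  expect_error(compare_distributions(numeric(0), 1), "non-empty")
  # calibration: same distribution rejects at about the nominal rate
  set.seed(7)
  rej <- mean(replicate(40, {
    compare_distributions(rnorm(200), rnorm(200))$p_value < 0.05
  }))
  expect_lt(rej, 0.15)
})

test_that("chi-squared proportion test matches hand computation", {
  flat <- proportion_trend_test(data.frame(biomarkers = c(5, 5),
                                           total = c(10, 10)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  split2 <- proportion_trend_test(data.frame(biomarkers = c(10, 0),
                                             total = c(10, 10)))
  expect_equal(split2$statistic, 20)  # sum((O - E)^2 / E) by hand
  flat3 <- proportion_trend_test(data.frame(biomarkers = c(2, 4, 6),
                                            total = c(10, 20, 30)))
  expect_equal(flat3$statistic, 0, tolerance = 1e-12)
  expect_error(proportion_trend_test(data.frame(biomarkers = 0, total = 5)),
               "2 groups")
  expect_error(proportion_trend_test(data.frame(biomarkers = c(0, 1),
                                                total = c(0, 5))), "total")
})

test_that("Spearman correlation is tie-aware and validated", {
  mono <- rank_correlation(1:10, (1:10)^3)
  expect_equal(mono$rho, 1)
  expect_equal(rank_correlation(1:10, -(1:10))$rho, -1)
  expect_error(rank_correlation(1:3, 1:4), "equal length")
  expect_error(rank_correlation(1:2, 2:1), "at least 3")
  set.seed(21)
  indep <- rank_correlation(rnorm(1000), rnorm(1000))
  expect_lt(abs(indep$rho), 0.1)
})

test_that("functional fractions use the class target union", {
  sets <- list(m1 = c("G1", "G2"), m2 = c("G2", "G3"))
  expect_equal(unname(functional_fraction(sets, "G1",
                                          classes = list(one = "m1"))), 0.5)
  expect_equal(unname(functional_fraction(sets, "ZZZ")), 0)
  expect_equal(unname(functional_fraction(sets, c("G1", "G2", "G3"))), 1)
  expect_true(is.na(functional_fraction(sets, "G1",
                                        classes = list(none = character(0)))))
  per <- functional_fraction(sets, "G2", denominator = "per_mirna_mean")
  expect_equal(unname(per), 0.5)  # both miRNAs hit 1 of their 2 targets
})

test_that("AUC is the tie-corrected concordance probability", {
  mk <- function(ref, case) {
    vals <- matrix(c(ref, case), nrow = 1,
                   dimnames = list("f", sprintf("s%d", seq_along(c(ref, case)))))
    expression_matrix(vals, stats::setNames(rep(c("pPCa", "mPCa"),
                                                c(length(ref), length(case))),
                                            colnames(vals)),
                      reference = "pPCa")
  }
  expect_equal(compute_auc(mk(c(1, 2, 3), c(4, 5, 6)), "f")$auc, 1)
  expect_equal(compute_auc(mk(c(1, 3), c(2, 4)), "f")$auc, 0.75)
  expect_equal(compute_auc(mk(rep(2, 3), rep(2, 4)), "f")$auc, 0.5)
  # a down-regulated marker still scores above 0.5 under auto orientation
  down <- compute_auc(mk(c(4, 5, 6), c(1, 2, 3)), "f", "auto")
  expect_equal(down$auc, 1)
  expect_equal(down$direction, "down_in_case")
  fixed <- compute_auc(mk(c(4, 5, 6), c(1, 2, 3)), "f", "fixed")
  expect_equal(fixed$auc, 1)
  expect_error(compute_auc(mk(1:2, 3:4), "missing"), "unknown feature")
  # brute-force concordant-pair oracle on random inputs
  set.seed(77)
  for (rep in 1:20) {
    ref <- sample(1:6, sample(2:8, 1), replace = TRUE)
    case <- sample(1:6, sample(2:8, 1), replace = TRUE)
    got <- compute_auc(mk(ref, case), "f", "auto")$auc
    a <- brute_auc(case, ref)
    expect_equal(got, max(a, 1 - a))
  }
})

test_that("mean AUC averages and validates", {
  expect_equal(mean_auc(c(0.5, 1)), 0.75)
  expect_equal(mean_auc(0.8), 0.8)
  expect_equal(mean_auc(list(list(auc = 0.6), list(auc = 0.8))), 0.7)
  expect_error(mean_auc(numeric(0)), "no AUC")
})
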