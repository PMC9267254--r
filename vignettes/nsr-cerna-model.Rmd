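---
title: "Single-line regulation in ceRNA networks: the model behind cernet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-line regulation in ceRNA networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernet)
```

## The model

Long non-coding RNAs (lncRNAs) and messenger RNAs (mRNAs) that share
microRNA (miRNA) binding sites compete for the same miRNA pool — the
competing endogenous RNA (ceRNA) hypothesis. `cernet` builds the
three-layer lncRNA–miRNA–mRNA network that this competition induces
and prioritizes miRNA biomarkers by a structural signal: *single-line
regulation*. A target regulated by exactly one miRNA is a vulnerable
site — there is no redundant regulator to buffer a perturbation — so a
miRNA that holds many such exclusive targets concentrates regulatory
power. Per miRNA the model counts

* `NSR-mRNA` — mRNA partners whose only miRNA regulator it is,
* `NSR-lncRNA` — likewise among lncRNA partners,
* `NSR-sponge = NSR-mRNA + NSR-lncRNA` — its single-line sponges,

where NSR stands for "number of single-line regulations". miRNAs whose
three counts are all significantly high against the network background
are the candidate biomarkers.

## Pipeline stages

1. **Pair ingestion** (`load_pairs`). Tab-separated regulator–target
   lists, one per target class. miRNA symbols are normalized to the
   `miR-`/`let-` convention with optional species-prefix stripping;
   duplicate pairs merge by unioning evidence sources and summing
   support counts, and the support filter (`min_support`, default 1)
   applies *after* merging — the most permissive reading when several
   databases contribute the same pair.
2. **ceRNA inference** (`infer_triplets`). Every (lncRNA, mRNA) pair
   sharing at least one miRNA is tested for overlap: with `N` miRNAs
   in the universe, `K` targeting the lncRNA, `n` targeting the mRNA
   and `k` shared, the p-value is the exact hypergeometric upper tail
   `P[X >= k]`. Benjamini–Hochberg correction runs over exactly this
   family (pairs with `k = 0` cannot form triplets and would only
   dilute the FDR family, so they are never tested). Each pair with
   adj.P `< alpha_triplet` (default 0.01) contributes one triplet per
   shared miRNA; significance is a pair property inherited by its
   triplets. The construction is purely structural — no
   expression-correlation filter.
3. **Differential expression** (`differential_expression`). A
   two-group screen with `adj.P < 0.05` and `|log2FC| > 1` (both
   strict), log2FC oriented case minus reference. The engine is
   interchangeable: `welch` (row-wise unequal-variance t-test) or
   `moderated` (the empirical-Bayes moderated t, delegated to limma);
   a precomputed DE table can be supplied instead (`read_de_table`).
4. **Condition-specific extraction**
   (`extract_condition_specific`). Triplets survive when their miRNA
   *and* their mRNA are differentially expressed; the surviving
   lncRNAs are the functional lncRNAs the model infers — they are not
   filtered on expression.
5. **NSR scoring** (`compute_nsr`, `nsr_significance`,
   `select_candidates`). The surviving triplets are projected onto
   deduplicated miRNA–mRNA and miRNA–lncRNA edge sets (an edge is a
   regulation, not a triplet count) and single-line counts are taken
   *within the condition-specific network* — the disease-specific
   wiring, not the global reference, is where vulnerability matters.
   Candidates must pass all three per-metric significance thresholds
   (raw p `< alpha_nsr`, default 0.05, no multiplicity correction —
   the selection rule is a fixed conjunction of three raw
   thresholds).

## Design choices at the genuinely open points

**The miRNA universe `N`.** The population from which both partner
sets are drawn is taken as the union of the two networks' miRNA sets.
An `intersection` option restricts `K` and `n` to the shared miRNAs
(keeping the hypergeometric bounds valid), and a `fixed` option
accepts an external census; sensitivity to the choice can be tested
directly.

**The signed-rank pairing.** A per-miRNA, per-metric p-value requires
a background to compare against. The default pairs miRNA *m*'s count
against every other miRNA's count in the condition-specific network
and computes the one-sided Wilcoxon signed-rank p-value on the
differences (alternative: median difference > 0) — the only pairing
that yields one p-value per miRNA per metric. Zero differences are
dropped (standard Wilcoxon convention). Because counts tie heavily,
the exact distribution is enumerated by dynamic programming over
doubled midranks for up to 25 nonzero differences — `stats` refuses
exact signed-rank p-values under ties, but the sign-assignment
enumeration remains well defined — and a tie-corrected normal
approximation with continuity correction takes over above. The
`empirical` alternative, `p = (1 + #{j : NSR_j >= NSR_m}) / n`, is a
transparent upper-tail rank probability that orders miRNAs
identically and serves as a cross-check.

**AUC orientation.** The per-marker AUC is the Mann–Whitney
concordance probability with ties counting one half. Discriminative
ability is direction-symmetric, so the default `auto` policy reports
`max(a, 1 - a)` with the implied direction — a marker down-regulated
in cases still scores above 0.5. A `fixed` policy follows the sign of
the log2 fold change instead.

**Determinism.** All outputs are sorted on primary keys
(lexicographic pair order, `nsr_sponge` descending with id
tie-breaks), so repeated runs are byte-identical.

## The synthetic benchmark

`simulation_config()` / `simulate_dataset()` generate data with the
structure the model assumes, so every stage is testable without any
external download. Three miRNA tiers:

* **Planted biomarkers** (default 5) each own 8 mRNA and 8 lncRNA
  partners and are down-regulated in the case group by `effect_size`
  (default 2 on the log2 scale, noise sd 0.5, 15 samples per group) —
  as are their partner mRNAs.
* **Hub miRNAs** (default 10) co-target every planted partner and a
  `module_frac` (0.4) fraction of background targets with probability
  0.9, and are never differentially expressed. This layer is
  essential, not decorative: a (lncRNA, mRNA) pair whose only shared
  regulator is the planted miRNA itself has an overlap p-value of
  `1/N`, which can never clear an FDR threshold of 0.01 — exclusive
  degree-1 partners are *structurally invisible* to the overlap test.
  Real miRNA–target data solve the same problem with their
  heavy-tailed co-targeting hubs; the generator reproduces that. The
  planted partners are therefore single-line *among differentially
  expressed regulators* — exactly the sense in which the model counts
  them, since NSR is computed on the extracted network from which the
  non-DE hubs have dropped out.
* **Background miRNAs** attach to module targets with probability
  0.08 and everywhere at the Erdős–Rényi `density` (0.01); 10 of them
  (and 40 module mRNAs) are down-regulated *decoys* — differentially
  expressed but without planted structure. They populate the
  condition-specific network with low-NSR profiles, providing the
  background the signed-rank test needs; without them every extracted
  miRNA would be a planted one, all counts would tie, and no
  significance could be assigned.

`collision_report()` lists planted partners that the random
background accidentally touched, so recovery analyses can condition
on clean plants. With `density = 0` the pipeline recovers the planted
counts exactly (an equality the test suite asserts, no tolerance).

What the generator does *not* emulate: array-specific noise (Gaussian
on the log2 scale only — the DE stage needs location shifts, nothing
more), realistic degree distributions beyond the hub layer, the
marginal distributions of any particular expression study, and
correlated expression between a miRNA and its targets. Passing the
recovery suite therefore shows the inference machinery is correct
under the model's own assumptions, not that those assumptions hold in
any given dataset.

## Validation problem sizes

The test suite exercises: exact-oracle comparisons for the
hypergeometric tail (all parameter combinations with `N <= 20`
against direct combinatorial summation), NSR (200 random networks of
up to 50 nodes against a brute-force degree scan), and AUC (200
random inputs against concordant-pair counting); the triplet-count
identity `|triplets| = sum of k over significant pairs` on simulated
instances; end-to-end planted-biomarker recovery on the default
configuration over 20 seeds (mean precision and recall at or above
0.9); and a null calibration (no planted structure, zero effect) in
which the candidate set must be empty in at least 18 of 20 seeds.

## A worked example

```{r example, eval = FALSE}
ds <- simulate_dataset(simulation_config(seed = 1))
res <- run_pipeline(ds)
res$global                     # inferred global ceRNA network
res$specific                   # condition-specific subnetwork
head(res$profiles)             # NSR counts, p-values, candidate calls
recovery_stats(res$candidates, ds$truth)
```

## Known limitations

* Pair-level significance is inherited by triplets; a miRNA-specific
  overlap contribution is not modelled.
* Only lncRNAs and mRNAs act as ceRNA components; circRNAs and
  pseudogenes are outside the current network.
* The signed-rank background is the set of co-extracted miRNAs, so
  p-values are relative to the condition-specific network at hand and
  not comparable across networks of very different size.
* With fewer than three miRNAs in the extracted network no
  significance can be assigned (p is set to 1 with a warning).
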