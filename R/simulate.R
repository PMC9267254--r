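#' Simulation configuration
#'
#' Parameters of the synthetic benchmark generator. The generated data
#' have the structure the model assumes: two bipartite miRNA-target
#' networks whose planted biomarker miRNAs hold single-line (among
#' disease-relevant regulators) mRNA and lncRNA partners, plus
#' two-group log2 expression matrices in which planted miRNAs and
#' their partner mRNAs are down-regulated in the case group.
#'
#' Three miRNA tiers are generated. *Planted* miRNAs carry the
#' biomarker signal: each owns `planted_single_line_mrna` mRNA and
#' `planted_single_line_lncrna` lncRNA partners targeted by no other
#' differentially expressed miRNA. *Hub* miRNAs co-target every
#' planted partner and a `module_frac` fraction of background targets
#' (each with probability `hub_edge_prob`); they are never
#' differentially expressed. This co-targeting layer mirrors the
#' heavy-tailed hub structure of real miRNA-target data and is what
#' makes (lncRNA, mRNA) pairs detectable by the shared-miRNA overlap
#' test -- a pair sharing a single miRNA has an overlap p-value of
#' 1/N, which no FDR threshold below that can ever accept.
#' *Background* miRNAs attach to module targets with probability
#' `bg_attach_prob` and everywhere at the Erdos-Renyi `density`;
#' `n_decoy_mirnas` of them (and `n_decoy_mrnas` module mRNAs) are
#' down-regulated decoys: differentially expressed but without
#' planted single-line structure, providing the background the
#' signed-rank test ranks candidates against.
#'
#' @param n_mirnas,n_mrnas,n_lncrnas node budgets per class.
#' @param density Erdos-Renyi background edge probability per side.
#' @param n_planted number of planted biomarker miRNAs.
#' @param planted_single_line_mrna,planted_single_line_lncrna
#'   single-line partners given to each planted miRNA.
#' @param n_hub_mirnas,hub_edge_prob,module_frac,bg_attach_prob hub
#'   co-targeting layer (see Details).
#' @param n_decoy_mirnas,n_decoy_mrnas down-regulated decoy features.
#' @param n_samples samples per group.
#' @param effect_size log2 fold-change magnitude of planted/decoy DE
#'   features (down in case).
#' @param noise_sd expression noise standard deviation (> 0).
#' @param baseline mean log2 expression.
#' @param seed RNG seed.
#' @return object of class `sim_config` (a validated list).
#' @export
simulation_config <- function(n_mirnas = 50, n_mrnas = 400, n_lncrnas = 200,
                              density = 0.01, n_planted = 5,
                              planted_single_line_mrna = 8,
                              planted_single_line_lncrna = 8,
                              n_hub_mirnas = 10, hub_edge_prob = 0.9,
                              module_frac = 0.4, bg_attach_prob = 0.08,
                              n_decoy_mirnas = 10, n_decoy_mrnas = 40,
                              n_samples = 15, effect_size = 2,
                              noise_sd = 0.5, baseline = 8, seed = 1) {
  cfg <- list(n_mirnas = n_mirnas, n_mrnas = n_mrnas, n_lncrnas = n_lncrnas,
              density = density, n_planted = n_planted,
              planted_single_line_mrna = planted_single_line_mrna,
              planted_single_line_lncrna = planted_single_line_lncrna,
              n_hub_mirnas = n_hub_mirnas, hub_edge_prob = hub_edge_prob,
              module_frac = module_frac, bg_attach_prob = bg_attach_prob,
              n_decoy_mirnas = n_decoy_mirnas, n_decoy_mrnas = n_decoy_mrnas,
              n_samples = n_samples, effect_size = effect_size,
              noise_sd = noise_sd, baseline = baseline, seed = seed)
  counts <- cfg[c("n_mirnas", "n_mrnas", "n_lncrnas", "n_planted",
                  "planted_single_line_mrna", "planted_single_line_lncrna",
                  "n_hub_mirnas", "n_decoy_mirnas", "n_decoy_mrnas",
                  "n_samples")]
  if (any(unlist(counts) < 0)) stop("all counts must be >= 0")
  probs <- cfg[c("density", "hub_edge_prob", "module_frac", "bg_attach_prob")]
  if (any(unlist(probs) < 0 | unlist(probs) > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (n_planted * planted_single_line_mrna > n_mrnas) {
    stop("planted mRNA partners exceed the mRNA node budget")
  }
  if (n_planted * planted_single_line_lncrna > n_lncrnas) {
    stop("planted lncRNA partners exceed the lncRNA node budget")
  }
  if (n_planted + n_hub_mirnas + n_decoy_mirnas > n_mirnas) {
    stop("planted + hub + decoy miRNAs exceed the miRNA node budget")
  }
  structure(cfg, class = "sim_config")
}

bernoulli_edges <- function(mirnas, targets, p) {
  if (!length(mirnas) || !length(targets) || p <= 0) {
    return(data.frame(mirna = character(0), target = character(0),
                      stringsAsFactors = FALSE))
  }
  hit <- which(stats::runif(length(mirnas) * length(targets)) < p)
  idx <- arrayInd(hit, c(length(mirnas), length(targets)))
  data.frame(mirna = mirnas[idx[, 1L]], target = targets[idx[, 2L]],
             stringsAsFactors = FALSE)
}

#' Generate a synthetic benchmark dataset
#'
#' Fully reproducible from `config$seed`. See [simulation_config()]
#' for what is planted and why.
#'
#' @param config a [simulation_config()].
#' @return object of class `synthetic_dataset`: `mrna_net` and
#'   `lncrna_net` ([build_network()] objects), `expr_mirna` and
#'   `expr_mrna` ([expression_matrix()] objects, groups pPCa
#'   reference / mPCa case), `truth` (planted miRNA ids),
#'   `planted_partners` (per planted miRNA, per class),
#'   `hub_mirnas`, `decoy_mirnas`, `decoy_mrnas`, `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  planted <- if (cfg$n_planted) sprintf("miR-P%02d", seq_len(cfg$n_planted)) else character(0)
  hubs <- if (cfg$n_hub_mirnas) sprintf("miR-H%02d", seq_len(cfg$n_hub_mirnas)) else character(0)
  n_bg_mir <- cfg$n_mirnas - cfg$n_planted - cfg$n_hub_mirnas
  bg_mir <- if (n_bg_mir) sprintf("miR-B%02d", seq_len(n_bg_mir)) else character(0)
  mirnas <- c(planted, hubs, bg_mir)

  mrnas <- sprintf("G%04d", seq_len(cfg$n_mrnas))
  lncrnas <- sprintf("L%04d", seq_len(cfg$n_lncrnas))
  npm <- cfg$n_planted * cfg$planted_single_line_mrna
  npl <- cfg$n_planted * cfg$planted_single_line_lncrna
  pm <- mrnas[seq_len(npm)]
  pl <- lncrnas[seq_len(npl)]
  partners_m <- if (cfg$n_planted) split(pm, rep(planted, each = cfg$planted_single_line_mrna)) else list()
  partners_l <- if (cfg$n_planted) split(pl, rep(planted, each = cfg$planted_single_line_lncrna)) else list()
  bg_mrnas <- setdiff(mrnas, pm)
  bg_lncrnas <- setdiff(lncrnas, pl)

  module_m <- bg_mrnas[stats::runif(length(bg_mrnas)) < cfg$module_frac]
  module_l <- bg_lncrnas[stats::runif(length(bg_lncrnas)) < cfg$module_frac]
  decoy_mir <- if (cfg$n_decoy_mirnas && length(bg_mir)) {
    sort(sample(bg_mir, min(cfg$n_decoy_mirnas, length(bg_mir))))
  } else character(0)
  decoy_mrna <- if (cfg$n_decoy_mrnas && length(module_m)) {
    sort(sample(module_m, min(cfg$n_decoy_mrnas, length(module_m))))
  } else character(0)

  side_edges <- function(partner_map, all_targets, module_targets) {
    parts <- list()
    if (length(partner_map)) {
      parts$planted <- data.frame(
        mirna = rep(names(partner_map), lengths(partner_map)),
        target = unlist(partner_map, use.names = FALSE),
        stringsAsFactors = FALSE)
      if (length(hubs)) {
        parts$anchor <- expand.grid(mirna = hubs,
                                    target = unlist(partner_map, use.names = FALSE),
                                    stringsAsFactors = FALSE)
      }
    }
    parts$hub_module <- bernoulli_edges(hubs, module_targets, cfg$hub_edge_prob)
    parts$bg_module <- bernoulli_edges(bg_mir, module_targets, cfg$bg_attach_prob)
    parts$er <- bernoulli_edges(mirnas, all_targets, cfg$density)
    do.call(rbind, parts)
  }
  medges <- side_edges(partners_m, mrnas, module_m)
  ledges <- side_edges(partners_l, lncrnas, module_l)

  expr_mat <- function(features, de_features) {
    n <- cfg$n_samples
    samples <- c(sprintf("pPCa_%02d", seq_len(n)), sprintf("mPCa_%02d", seq_len(n)))
    vals <- matrix(stats::rnorm(length(features) * 2 * n, cfg$baseline,
                                cfg$noise_sd),
                   nrow = length(features),
                   dimnames = list(features, samples))
    if (length(de_features)) {
      vals[de_features, (n + 1):(2 * n)] <-
        vals[de_features, (n + 1):(2 * n)] - cfg$effect_size
    }
    groups <- stats::setNames(rep(c("pPCa", "mPCa"), each = n), samples)
    expression_matrix(vals, groups, reference = "pPCa")
  }
  expr_mirna <- expr_mat(mirnas, c(planted, decoy_mir))
  expr_mrna <- expr_mat(mrnas, c(pm, decoy_mrna))

  mrna_net <- build_network(
    data.frame(regulator = medges$mirna, target = medges$target,
               stringsAsFactors = FALSE), target_class = "mRNA")
  lncrna_net <- build_network(
    data.frame(regulator = ledges$mirna, target = ledges$target,
               stringsAsFactors = FALSE), target_class = "lncRNA")

  structure(list(mrna_net = mrna_net, lncrna_net = lncrna_net,
                 expr_mirna = expr_mirna, expr_mrna = expr_mrna,
                 truth = planted,
                 planted_partners = list(mRNA = partners_m, lncRNA = partners_l),
                 hub_mirnas = hubs, decoy_mirnas = decoy_mir,
                 decoy_mrnas = decoy_mrna, config = cfg),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("synthetic ceRNA dataset (seed %d): %d planted ",
                     "biomarker miRNAs, %d decoys\n"),
              x$config$seed, length(x$truth), length(x$decoy_mirnas)))
  print(x$mrna_net)
  print(x$lncrna_net)
  invisible(x)
}

#' Report collisions on planted single-line partners
#'
#' A planted partner "collides" when a miRNA outside its design (not
#' its owner, not a hub) acquires an edge to it through the random
#' background, raising its degree beyond the planted structure.
#' Recovery tests can condition on clean plants using this table.
#'
#' @param ds a [simulate_dataset()] result.
#' @return data.frame `target`, `target_class`, `owner`,
#'   `extra_degree` (one row per collided partner; zero rows when
#'   clean).
#' @export
collision_report <- function(ds) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  one_side <- function(net, partner_map, class) {
    rows <- list()
    for (owner in names(partner_map)) {
      for (t in partner_map[[owner]]) {
        regs <- net$edges$mirna[net$edges$target == t]
        extra <- setdiff(regs, c(owner, ds$hub_mirnas))
        if (length(extra)) {
          rows[[length(rows) + 1L]] <- data.frame(
            target = t, target_class = class, owner = owner,
            extra_degree = length(extra), stringsAsFactors = FALSE)
        }
      }
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(target = character(0), target_class = character(0),
                 owner = character(0), extra_degree = integer(0),
                 stringsAsFactors = FALSE)
  }
  out <- rbind(one_side(ds$mrna_net, ds$planted_partners$mRNA, "mRNA"),
               one_side(ds$lncrna_net, ds$planted_partners$lncRNA, "lncRNA"))
  rownames(out) <- NULL
  out
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits `mirna_mrna_pairs.tsv`, `mirna_lncrna_pairs.tsv`,
#' `expr_mirna.tsv`, `expr_mrna.tsv`, `labels.tsv` and `truth.tsv`
#' under `dir`, in the formats the loaders read back.
#'
#' @param ds a [simulate_dataset()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory path.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wpairs <- function(net, file) {
    utils::write.table(net$edges, file.path(dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  wpairs(ds$mrna_net, "mirna_mrna_pairs.tsv")
  wpairs(ds$lncrna_net, "mirna_lncrna_pairs.tsv")
  wexpr <- function(expr, file) {
    tab <- data.frame(feature = rownames(expr$values), expr$values,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  wexpr(ds$expr_mirna, "expr_mirna.tsv")
  wexpr(ds$expr_mrna, "expr_mrna.tsv")
  labels <- data.frame(sample = names(ds$expr_mirna$groups),
                       group = as.character(ds$expr_mirna$groups),
                       stringsAsFactors = FALSE)
  utils::write.table(labels, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(mirna = ds$truth),
                     file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(dir)
}
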