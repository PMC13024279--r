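# Synthetic fixture generator with planted ground truth: confidence-weighted
# networks with planted hubs, DEG tables with planted resistance genes, drug
# catalogs with planted sensitive/resistant agents.

#' Configuration for the synthetic study generator
#'
#' The defaults define the study conditions used throughout the package's
#' recovery tests: 300 genes, 8 planted hubs, 6 planted sensitive and 6
#' planted resistant drugs among 60 decoys.
#'
#' @param n_genes Number of genes. Default 300.
#' @param n_hubs Number of planted hub genes. Default 8.
#' @param hub_attach_fraction Fraction of all nodes each planted hub is
#'   additionally wired to. Default 0.3.
#' @param edge_prob Erdos-Renyi background edge probability. Default 0.03.
#' @param confidence_range Uniform range for edge confidences.
#'   Default `c(0.4, 0.999)` so the 0.7 high-confidence cut is non-trivial.
#' @param log2fc_sd SD of null-gene log2 fold changes. Default 0.3.
#' @param de_fraction Fraction of background genes that are genuinely
#'   perturbed (large fold change, small padj), emulating the effect-size /
#'   p-value coupling of real differential-expression output. Default 0.65.
#'   At 0 the background is a pure null: `N(0, log2fc_sd)` fold changes
#'   with `Uniform(0, 1)` padj.
#' @param perturbed_fc_sd SD of perturbed-gene log2 fold changes.
#'   Default 1.5.
#' @param planted_fc Log2 fold change of planted hubs (upregulated, so an
#'   inhibitor's sensitivity score is positive). Default 2.
#' @param n_drugs Total drug count. Default 72.
#' @param n_planted_sensitive Planted sensitive (inhibitor) drugs; an equal
#'   number of planted resistant (agonist) drugs is generated. Default 6.
#' @param potency_range_nm Potency range of planted drugs (nM).
#'   Default `c(10, 300)`.
#' @param decoy_potency_range_nm Potency range of decoy drugs (nM).
#'   Default `c(500, 5000)`.
#' @param seed RNG seed. Default 1.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 300, n_hubs = 8, hub_attach_fraction = 0.3,
                             edge_prob = 0.03, confidence_range = c(0.4, 0.999),
                             log2fc_sd = 0.3, de_fraction = 0.65,
                             perturbed_fc_sd = 1.5, planted_fc = 2,
                             n_drugs = 72, n_planted_sensitive = 6,
                             potency_range_nm = c(10, 300),
                             decoy_potency_range_nm = c(500, 5000), seed = 1) {
  stopifnot(n_hubs < n_genes, planted_fc >= 1,
            hub_attach_fraction > 0, hub_attach_fraction <= 1,
            de_fraction >= 0, de_fraction <= 1,
            confidence_range[1] <= confidence_range[2],
            potency_range_nm[1] <= potency_range_nm[2],
            decoy_potency_range_nm[1] <= decoy_potency_range_nm[2],
            n_drugs >= 2 * n_planted_sensitive)
  structure(as.list(environment()), class = "synthetic_config")
}

syn_genes <- function(cfg) sprintf("G%04d", seq_len(cfg$n_genes))

#' Generate a confidence-weighted network with planted hubs
#'
#' A background Erdos-Renyi graph at `edge_prob` over all genes; each of the
#' `n_hubs` designated hub genes is additionally wired to
#' `hub_attach_fraction` of all nodes. Edge confidences are drawn uniformly
#' from `confidence_range`.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `edges` (tibble `node_a`, `node_b`, `confidence`) and
#'   `truth` (list with `hub_genes`).
#' @export
generate_network <- function(cfg) {
  genes <- syn_genes(cfg)
  hubs <- genes[seq_len(cfg$n_hubs)]
  with_seed(cfg$seed, {
    # background ER edges over the upper triangle
    pairs <- utils::combn(cfg$n_genes, 2)
    keep <- stats::runif(ncol(pairs)) < cfg$edge_prob
    ea <- genes[pairs[1, keep]]
    eb <- genes[pairs[2, keep]]
    # extra hub attachments
    for (h in seq_len(cfg$n_hubs)) {
      others <- setdiff(seq_len(cfg$n_genes), h)
      n_extra <- round(cfg$hub_attach_fraction * cfg$n_genes)
      tgt <- sample(others, min(n_extra, length(others)))
      ea <- c(ea, rep(genes[h], length(tgt)))
      eb <- c(eb, genes[tgt])
    }
    ed <- merge_edges(tibble(node_a = ea, node_b = eb, confidence = 0))
    ed$confidence <- stats::runif(nrow(ed), cfg$confidence_range[1],
                                  cfg$confidence_range[2])
    list(edges = ed, truth = list(hub_genes = hubs))
  })
}

#' Generate a DEG table with planted resistance genes
#'
#' Planted hubs get `log2fc = +planted_fc` and `padj ~ Uniform(0, 0.01)`,
#' guaranteeing retention at the conventional thresholds. Background genes
#' are a mixture: a `de_fraction` share are genuinely perturbed
#' (`log2fc ~ N(0, perturbed_fc_sd)`, `padj ~ Uniform(0, 0.02)`), the rest
#' null (`log2fc ~ N(0, log2fc_sd)`, `padj ~ Uniform(0, 1)`).
#'
#' @param cfg A [synthetic_config()].
#' @param truth Truth list from [generate_network()].
#' @return DEG tibble `gene`, `log2fc`, `padj`, `base_expr` for all
#'   `n_genes` genes (unfiltered).
#' @export
generate_deg_table <- function(cfg, truth) {
  genes <- syn_genes(cfg)
  is_hub <- genes %in% truth$hub_genes
  with_seed(cfg$seed + 1, {
    n_bg <- sum(!is_hub)
    perturbed <- stats::runif(n_bg) < cfg$de_fraction
    fc <- numeric(n_bg)
    padj <- numeric(n_bg)
    fc[perturbed] <- stats::rnorm(sum(perturbed), 0, cfg$perturbed_fc_sd)
    padj[perturbed] <- stats::runif(sum(perturbed), 0, 0.02)
    fc[!perturbed] <- stats::rnorm(sum(!perturbed), 0, cfg$log2fc_sd)
    padj[!perturbed] <- stats::runif(sum(!perturbed))
    df <- tibble(gene = genes, log2fc = NA_real_, padj = NA_real_,
                 base_expr = stats::rlnorm(cfg$n_genes, meanlog = 4, sdlog = 1))
    df$log2fc[is_hub] <- cfg$planted_fc
    df$padj[is_hub] <- stats::runif(cfg$n_hubs, 0, 0.01)
    df$log2fc[!is_hub] <- fc
    df$padj[!is_hub] <- padj
    df
  })
}

#' Generate a drug catalog with planted sensitive and resistant agents
#'
#' Planted sensitive drugs are inhibitors hitting 2-3 planted hubs at
#' `potency_range_nm`; an equal number of planted resistant drugs are
#' agonists of planted hubs; the remaining decoys are inhibitors of 1-3
#' random non-hub genes at decoy potency.
#'
#' @param cfg A [synthetic_config()].
#' @param truth Truth list from [generate_network()].
#' @return List with `drug_targets` (tibble in [read_drug_target_table()]
#'   layout plus `activity_nm`) and `truth` extended with `sensitive_drugs`
#'   and `resistant_drugs`.
#' @export
generate_drug_table <- function(cfg, truth) {
  genes <- syn_genes(cfg)
  hubs <- truth$hub_genes
  non_hubs <- setdiff(genes, hubs)
  n_sens <- cfg$n_planted_sensitive
  n_res <- n_sens
  n_decoy <- cfg$n_drugs - n_sens - n_res
  ids <- sprintf("D%03d", seq_len(cfg$n_drugs))
  sens_ids <- ids[seq_len(n_sens)]
  res_ids <- ids[n_sens + seq_len(n_res)]
  decoy_ids <- ids[n_sens + n_res + seq_len(n_decoy)]
  with_seed(cfg$seed + 2, {
    mk <- function(id, targets, pot_range, mech) {
      tibble(drug_id = id, drug_name = paste0("drug_", id),
             target_gene = targets,
             activity_nm = stats::runif(length(targets), pot_range[1], pot_range[2]),
             activity_type = "IC50", mechanism = mech)
    }
    rows <- c(
      purrr::map(sens_ids, function(id) {
        mk(id, sample(hubs, sample(2:min(3, length(hubs)), 1)),
           cfg$potency_range_nm, "KINASE INHIBITOR")
      }),
      purrr::map(res_ids, function(id) {
        mk(id, sample(hubs, sample(2:min(3, length(hubs)), 1)),
           cfg$potency_range_nm, "RECEPTOR AGONIST")
      }),
      purrr::map(decoy_ids, function(id) {
        mk(id, sample(non_hubs, sample(1:3, 1)),
           cfg$decoy_potency_range_nm, "ENZYME INHIBITOR")
      })
    )
    dt <- purrr::list_rbind(rows)
    truth$sensitive_drugs <- paste0("drug_", sens_ids)
    truth$resistant_drugs <- paste0("drug_", res_ids)
    list(drug_targets = dt, truth = truth)
  })
}

#' Label a ranked drug table against the planted truth
#'
#' Builds a validation-pair table (one row per planted drug) with the
#' actual effect from the truth and the predicted effect, rank and
#' candidate count from the ranking, directly consumable by
#' [validate_predictions()].
#'
#' @param truth Truth list containing `sensitive_drugs`/`resistant_drugs`.
#' @param ranked Output of [rank_drugs()].
#' @param dataset Label for the `dataset` column. Default "synthetic".
#' @return Validation-pair tibble with a `correct` column.
#' @export
generate_validation_pairs <- function(truth, ranked, dataset = "synthetic") {
  planted <- c(truth$sensitive_drugs, truth$resistant_drugs)
  actual <- rep(c("sensitive", "resistant"),
                c(length(truth$sensitive_drugs), length(truth$resistant_drugs)))
  idx <- match(toupper(planted), toupper(ranked$drug_name))
  df <- tibble(
    dataset = dataset, context = "synthetic", drug_name = planted,
    actual_effect = actual,
    predicted_effect = ifelse(is.na(idx), "not_observed",
                              ranked$predicted_effect[idx]),
    rank_obs = ifelse(is.na(idx), NA_integer_, ranked$rank[idx]),
    n_cand = ifelse(is.na(idx), NA_integer_, nrow(ranked))
  )
  df$predicted_effect[df$predicted_effect == "neutral"] <- "not_observed"
  df$correct <- df$predicted_effect == df$actual_effect
  df
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper chaining [generate_network()],
#' [generate_deg_table()] and [generate_drug_table()].
#'
#' @param cfg A [synthetic_config()].
#' @return List with `edges`, `degs` (unfiltered), `drug_targets`, `truth`.
#' @export
simulate_study <- function(cfg = synthetic_config()) {
  net <- generate_network(cfg)
  degs <- generate_deg_table(cfg, net$truth)
  drugs <- generate_drug_table(cfg, net$truth)
  list(edges = net$edges, degs = degs, drug_targets = drugs$drug_targets,
       truth = drugs$truth, config = cfg)
}
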