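# Drug-target matching, signed sensitivity scoring, ranking, tier filters.

#' Map a mechanism-of-action string to an effect multiplier
#'
#' Case-insensitive keyword rule: inhibitory/suppressive mechanisms
#' (inhibitor, antagonist, blocker, suppress, negative modulator, degrader)
#' map to `+1`; activating mechanisms (agonist, activator, opener, positive
#' modulator, inducer) map to `-1`. "antagonist" is checked before
#' "agonist" because of the substring overlap. Anything else is
#' indeterminate (`NA`) and such drugs are excluded from ranking.
#'
#' @param mechanism Character vector of mechanism strings.
#' @return Integer vector of `+1`, `-1` or `NA`.
#' @export
effect_multiplier <- function(mechanism) {
  m <- tolower(mechanism)
  pos <- c("inhibitor", "antagonist", "blocker", "suppress", "negative modulator", "degrader")
  neg <- c("agonist", "activator", "opener", "positive modulator", "inducer")
  vapply(m, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_integer_)
    if (any(vapply(pos, grepl, logical(1), x = s, fixed = TRUE))) return(1L)
    if (any(vapply(neg, grepl, logical(1), x = s, fixed = TRUE))) return(-1L)
    NA_integer_
  }, integer(1), USE.NAMES = FALSE)
}

aggregate_activity <- function(x, method) {
  switch(method,
    median = stats::median(x),
    geomean = exp(mean(log(x))),
    min = min(x),
    abort(sprintf("Unknown activity aggregation '%s'.", method))
  )
}

#' Score all drugs against a hubness table
#'
#' For each drug, targets are matched by upper-cased gene symbol against the
#' network nodes (targets outside the network contribute nothing). Multiple
#' activity measurements per (drug, target) pair are aggregated first
#' (median nM by default). Per matched target `t` and metric `j` the
#' contribution is `(log2fc_t / activity_nm_t) * Z'_tj * 100 * W_j`; summed
#' over targets and metrics this equals
#' `100 * sum_t (log2fc_t / activity_nm_t) * TIHS_t`, and both forms are
#' computed and asserted equal. The signed sensitivity score is
#' `total_score * effect_multiplier`; positive predicts sensitivity in the
#' resistant state.
#'
#' @param drug_targets Tibble from [read_drug_target_table()].
#' @param hub A `tihs_hubness` tibble from [compute_tihs()].
#' @param degs The DEG tibble used to build the network (supplies log2fc).
#' @param weights The `tihs_weights` vector used for the hubness table.
#' @param nm The `tihs_normalized` object (shifted Z-scores).
#' @param aggregate Activity aggregation per (drug, target):
#'   `"median"` (default), `"geomean"` or `"min"`.
#' @return A tibble of per-drug score records: `drug_id`, `drug_name`,
#'   `n_targets`, `matched_genes`, `mean_activity_nm`, `total_score`,
#'   `effect_multiplier`, `sensitivity_score`, plus a `matched_targets`
#'   list-column of per-target detail. Indeterminate-mechanism drugs are
#'   dropped with a warning.
#' @export
score_drugs <- function(drug_targets, hub, degs, weights, nm,
                        aggregate = c("median", "geomean", "min")) {
  aggregate <- match.arg(aggregate)
  check_weights(weights)
  deg_fc <- stats::setNames(degs$log2fc, norm_gene(degs$gene))
  tihs_v <- stats::setNames(hub$tihs, hub$gene)
  wv <- stats::setNames(weights$weight, weights$metric)[nm$metrics]

  dt <- dplyr::mutate(drug_targets, target_gene = norm_gene(.data$target_gene))
  mech <- dt |>
    dplyr::distinct(.data$drug_id, .data$drug_name, .data$mechanism) |>
    dplyr::group_by(.data$drug_id, .data$drug_name) |>
    dplyr::summarise(mechanism = paste(unique(.data$mechanism), collapse = "; "),
                     .groups = "drop") |>
    dplyr::mutate(mult = effect_multiplier(.data$mechanism))
  n_indet <- sum(is.na(mech$mult))
  if (n_indet > 0) {
    warn(sprintf("%d drug(s) with indeterminate mechanism excluded from ranking.", n_indet))
  }
  mech <- dplyr::filter(mech, !is.na(.data$mult))

  # aggregate multiple activity measurements per (drug, target) pair
  agg <- dt |>
    dplyr::group_by(.data$drug_id, .data$target_gene) |>
    dplyr::summarise(activity_nm = aggregate_activity(.data$activity_nm, aggregate),
                     .groups = "drop")

  rows <- purrr::map(seq_len(nrow(mech)), function(i) {
    id <- mech$drug_id[i]
    tg <- dplyr::filter(agg, .data$drug_id == id)
    matched <- tg$target_gene %in% names(tihs_v)
    mt <- tg[matched, ]
    if (nrow(mt) == 0) {
      return(tibble(
        drug_id = id, drug_name = mech$drug_name[i], n_targets = 0L,
        matched_genes = "", mean_activity_nm = NA_real_,
        total_score = 0, effect_multiplier = mech$mult[i],
        sensitivity_score = 0, matched_targets = list(tibble())
      ))
    }
    fc <- unname(deg_fc[mt$target_gene])
    ratio <- fc / mt$activity_nm
    # factored form: 100 * sum_t ratio_t * TIHS_t
    total_factored <- 100 * sum(ratio * unname(tihs_v[mt$target_gene]))
    # per-metric accumulation over target x metric combinations
    zs <- nm$z_shifted[mt$target_gene, , drop = FALSE]
    total_permetric <- sum((ratio * zs) %*% (100 * wv))
    if (abs(total_permetric - total_factored) >
        1e-9 * max(1, abs(total_factored))) {
      abort("Internal inconsistency: per-metric and TIHS-factored drug scores disagree.")
    }
    detail <- tibble(gene = mt$target_gene, log2fc = fc,
                     activity_nm = mt$activity_nm,
                     contribution = 100 * ratio * unname(tihs_v[mt$target_gene]))
    tibble(
      drug_id = id, drug_name = mech$drug_name[i], n_targets = nrow(mt),
      matched_genes = paste(sort(mt$target_gene), collapse = ","),
      mean_activity_nm = mean(mt$activity_nm),
      total_score = total_permetric, effect_multiplier = mech$mult[i],
      sensitivity_score = total_permetric * mech$mult[i],
      matched_targets = list(detail)
    )
  })
  purrr::list_rbind(rows)
}

#' Rank scored drugs by sensitivity score
#'
#' Sorts by sensitivity score descending, with ties broken by number of
#' matched targets descending then drug name ascending. Rank 1 is the best
#' candidate; `rank_fraction = rank / N`, the drug's rank expressed as a
#' uniform-null tail probability.
#'
#' @param records Output of [score_drugs()].
#' @return The records with `rank`, `rank_fraction` and
#'   `predicted_effect` (`"sensitive"` if the score is positive,
#'   `"resistant"` if negative, `"neutral"` at 0), sorted.
#' @export
rank_drugs <- function(records) {
  if (nrow(records) == 0) abort("No scored drugs to rank.")
  out <- records |>
    dplyr::arrange(dplyr::desc(.data$sensitivity_score),
                   dplyr::desc(.data$n_targets), .data$drug_name) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  rank_fraction = .data$rank / dplyr::n(),
                  predicted_effect = dplyr::case_when(
                    .data$sensitivity_score > 0 ~ "sensitive",
                    .data$sensitivity_score < 0 ~ "resistant",
                    TRUE ~ "neutral"))
  class(out) <- c("tihs_ranking", class(out))
  out
}

#' Apply the three-tier false-positive control
#'
#' Tier 1 (topology/ranking): positive sensitivity score and rank within the
#' top `top_fraction` of all evaluated agents. Tier 2 (target multiplicity):
#' at least `min_targets` matched topological targets, deprioritizing
#' single-target agents prone to bypass resistance. Tier 3
#' (biological/pharmacokinetic feasibility): every matched target shows
#' detectable expression (`>= min_expression`, when an expression table is
#' supplied) and the drug's mean matched-target potency does not exceed its
#' clinically achievable Cmax (when a Cmax table is supplied; drugs absent
#' from the table pass with a warning). The mean matched-target potency is
#' used as a proxy for an in vitro IC50 and labelled as such. No rows are
#' dropped; all flags are retained.
#'
#' @param ranked Output of [rank_drugs()].
#' @param top_fraction Tier-1 rank fraction cutoff. Default 0.10.
#' @param min_targets Tier-2 minimum matched targets. Default 2.
#' @param expression Optional tibble `gene`, `expression` of endogenous
#'   expression levels.
#' @param min_expression Tier-3 expression floor (in the units of
#'   `expression`). Default 1.
#' @param cmax Optional tibble from [read_cmax_table()].
#' @return `ranked` with logical `tier1_pass`, `tier2_pass`, `tier3_pass`
#'   and `pass_all` columns.
#' @export
apply_filters <- function(ranked, top_fraction = 0.10, min_targets = 2,
                          expression = NULL, min_expression = 1, cmax = NULL) {
  if (nrow(ranked) == 0) abort("`ranked` is empty.")
  stopifnot(top_fraction > 0, top_fraction <= 1, min_targets >= 1)
  out <- dplyr::mutate(ranked,
    tier1_pass = .data$sensitivity_score > 0 & .data$rank_fraction <= top_fraction,
    tier2_pass = .data$n_targets >= min_targets)
  expr_ok <- rep(TRUE, nrow(out))
  if (!is.null(expression)) {
    assert_cols(expression, c("gene", "expression"), "expression table")
    ev <- stats::setNames(expression$expression, norm_gene(expression$gene))
    expr_ok <- vapply(out$matched_targets, function(mt) {
      if (nrow(mt) == 0) return(FALSE)
      e <- ev[mt$gene]
      all(!is.na(e) & e >= min_expression)
    }, logical(1))
  }
  cmax_ok <- rep(TRUE, nrow(out))
  if (!is.null(cmax)) {
    cv <- stats::setNames(cmax$cmax_nm, cmax$drug_id)
    known <- out$drug_id %in% names(cv)
    if (any(!known)) {
      warn(sprintf("%d drug(s) absent from the Cmax table pass tier 3 by default.", sum(!known)))
    }
    cmax_ok[known] <- out$mean_activity_nm[known] <= unname(cv[out$drug_id[known]])
    cmax_ok[known & is.na(out$mean_activity_nm)] <- FALSE
  }
  out$tier3_pass <- expr_ok & cmax_ok
  out$pass_all <- out$tier1_pass & out$tier2_pass & out$tier3_pass
  out
}

#' Intersect per-dataset passing-candidate sets
#'
#' Case-normalized set intersection of drug names across datasets, plus the
#' full membership matrix for Venn-style reporting.
#'
#' @param pass_lists Named list of character vectors of passing drug names
#'   (one per dataset).
#' @return List with `shared` (character vector of drugs present in every
#'   list) and `membership` (tibble `drug` x one logical column per dataset).
#' @export
intersect_candidates <- function(pass_lists) {
  if (length(pass_lists) < 1) abort("Need at least one candidate list.")
  lists <- purrr::map(pass_lists, ~ unique(toupper(trimws(.x))))
  nm <- names(lists) %||% paste0("dataset", seq_along(lists))
  names(lists) <- nm
  all_drugs <- sort(unique(unlist(lists)))
  membership <- tibble(drug = all_drugs)
  for (d in nm) membership[[d]] <- all_drugs %in% lists[[d]]
  shared <- if (length(all_drugs) == 0) character(0) else {
    all_drugs[rowSums(as.matrix(membership[, nm, drop = FALSE])) == length(nm)]
  }
  list(shared = shared, membership = membership)
}

#' Fold difference between two IC50 (or other potency) values
#'
#' Reporting helper: the ratio of the less potent to the more potent value,
#' e.g. a parental vs resensitized IC50 pair.
#'
#' @param a,b Positive potency values in the same units.
#' @return `max(a, b) / min(a, b)`.
#' @export
fold_difference <- function(a, b) {
  if (any(c(a, b) <= 0)) abort("Potency values must be positive.")
  max(a, b) / min(a, b)
}
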