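#' Run the full hubness-to-drug-ranking pipeline
#'
#' Chains network construction, the five centralities, Z-shift
#' normalization, weight derivation (or locked externally supplied
#' weights), TIHS, drug scoring, ranking and the three-tier filter.
#'
#' @param degs Filtered DEG tibble (see [read_deg_table()]).
#' @param edges Edge tibble (see [read_string_links()]).
#' @param drug_targets Drug-target tibble with `activity_nm` (see
#'   [read_drug_target_table()]).
#' @param weights Optional locked `tihs_weights` vector; when supplied,
#'   weight derivation is skipped (the cross-cohort averaged vector is
#'   normally locked before application runs).
#' @param weights_mode Mode for [derive_weights()] when deriving.
#' @param min_confidence Edge confidence threshold. Default 0.7.
#' @param restrict_to_lcc See [build_network()]. Default `TRUE`.
#' @param epc_realizations EPC percolation realizations. Default 1000.
#' @param seed RNG seed (EPC).
#' @param top_fraction,min_targets,expression,min_expression,cmax Passed to
#'   [apply_filters()].
#' @param aggregate Activity aggregation mode for [score_drugs()].
#' @return Object of class `tihs_result`: list with `network`, `centrality`,
#'   `normalized`, `weights`, `hubness`, `ranked`, and `counts`.
#' @export
run_tihs <- function(degs, edges, drug_targets, weights = NULL,
                     weights_mode = c("std_share", "pca_loading"),
                     min_confidence = 0.7, restrict_to_lcc = TRUE,
                     epc_realizations = 1000, seed = NULL,
                     top_fraction = 0.10, min_targets = 2,
                     expression = NULL, min_expression = 1, cmax = NULL,
                     aggregate = "median") {
  weights_mode <- match.arg(weights_mode)
  net <- build_network(degs, edges, min_confidence = min_confidence,
                       restrict_to_lcc = restrict_to_lcc)
  cm <- compute_centralities(net, epc_realizations = epc_realizations, seed = seed)
  nmz <- zscore_shift(cm)
  w <- if (is.null(weights)) {
    derive_weights(nmz, cm, mode = weights_mode)
  } else {
    inform("Using supplied (locked) weight vector; derivation skipped.")
    check_weights(weights)
  }
  hub <- compute_tihs(nmz, w, cm = cm)
  scores <- score_drugs(drug_targets, hub, degs, w, nmz, aggregate = aggregate)
  ranked <- rank_drugs(scores)
  ranked <- apply_filters(ranked, top_fraction = top_fraction,
                          min_targets = min_targets, expression = expression,
                          min_expression = min_expression, cmax = cmax)
  structure(list(
    network = net, centrality = cm, normalized = nmz, weights = w,
    hubness = hub, ranked = ranked,
    counts = c(net$counts,
               drugs_scored = nrow(ranked),
               tier1 = sum(ranked$tier1_pass),
               pass_all = sum(ranked$pass_all))
  ), class = "tihs_result")
}

#' @export
print.tihs_result <- function(x, ...) {
  cat(sprintf("<tihs_result> network %d nodes / %d edges; %d drugs scored, %d tier-1, %d pass all tiers\n",
              x$counts[["nodes"]], x$counts[["edges"]], x$counts[["drugs_scored"]],
              x$counts[["tier1"]], x$counts[["pass_all"]]))
  cat("weights: ", paste(sprintf("%s=%.3f", x$weights$metric, x$weights$weight),
                         collapse = " "), "\n")
  invisible(x)
}
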