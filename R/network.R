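#' Build the DEG-induced high-confidence resistance network
#'
#' Takes a filtered DEG table and a confidence-weighted edge list and builds
#' the induced subgraph over the DEG gene symbols: an edge is retained only
#' if both endpoints are DEGs and its confidence is at least
#' `min_confidence`; nodes are the DEG genes incident to at least one
#' retained edge (isolated DEGs carry no usable topology and are reported
#' separately). By default only the largest connected component is kept,
#' because eigenvector centrality is ill-behaved across disconnected
#' components; ties between equal-sized components go to the component
#' containing the alphabetically first node.
#'
#' @param degs DEG tibble from [read_deg_table()] (columns `gene`, `log2fc`,
#'   `padj`, optionally `base_expr`).
#' @param edges Edge tibble from [read_string_links()] (columns `node_a`,
#'   `node_b`, `confidence`).
#' @param min_confidence Minimum edge confidence (inclusive). Default 0.7.
#' @param restrict_to_lcc Keep only the largest connected component.
#'   Default `TRUE`.
#' @return An object of class `resistance_network`: a list with `graph`
#'   (an igraph graph whose vertices carry `log2fc`/`padj`), `nodes` and
#'   `edges` tibbles, `excluded_degs` (DEGs with no qualifying edge), and
#'   `counts`.
#' @export
build_network <- function(degs, edges, min_confidence = 0.7, restrict_to_lcc = TRUE) {
  if (nrow(degs) == 0) abort("`degs` is empty.")
  if (nrow(edges) == 0) abort("`edges` is empty.")
  assert_cols(degs, c("gene", "log2fc", "padj"), "DEG table")
  assert_cols(edges, c("node_a", "node_b", "confidence"), "edge list")
  degs <- dplyr::mutate(degs, gene = norm_gene(.data$gene)) |> dedup_degs()
  ed <- merge_edges(dplyr::mutate(edges,
                                  node_a = norm_gene(.data$node_a),
                                  node_b = norm_gene(.data$node_b)))
  deg_genes <- degs$gene
  ed <- dplyr::filter(ed, .data$confidence >= min_confidence,
                      .data$node_a %in% deg_genes, .data$node_b %in% deg_genes)
  if (nrow(ed) == 0) {
    overlap <- length(intersect(deg_genes, unique(c(edges$node_a, edges$node_b))))
    abort(sprintf(
      "Empty network: no edge has both endpoints among the %d DEGs at confidence >= %g (%d DEG symbols appear in the edge list at all).",
      length(deg_genes), min_confidence, overlap))
  }
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  if (restrict_to_lcc) {
    comp <- igraph::components(g)
    sizes <- comp$csize
    best <- which(sizes == max(sizes))
    if (length(best) > 1) {
      # tie-break: component containing the alphabetically first node
      firsts <- vapply(best, function(k) min(names(comp$membership)[comp$membership == k]), "")
      best <- best[order(firsts)][1]
    }
    g <- igraph::induced_subgraph(g, which(comp$membership == best))
  }
  vnames <- igraph::V(g)$name
  ann <- degs[match(vnames, degs$gene), ]
  igraph::V(g)$log2fc <- ann$log2fc
  igraph::V(g)$padj <- ann$padj
  el <- igraph::as_data_frame(g, what = "edges")
  net <- structure(list(
    graph = g,
    nodes = tibble(gene = vnames, log2fc = ann$log2fc, padj = ann$padj),
    edges = tibble(node_a = el$from, node_b = el$to, confidence = el$confidence),
    excluded_degs = setdiff(deg_genes, vnames),
    counts = c(degs = length(deg_genes), nodes = length(vnames), edges = nrow(el))
  ), class = "resistance_network")
  inform(sprintf("Network: %d nodes, %d edges (from %d DEGs; %d DEGs without qualifying edges%s).",
                 length(vnames), nrow(el), length(deg_genes),
                 length(net$excluded_degs),
                 if (restrict_to_lcc) "; restricted to LCC" else ""))
  net
}

#' @export
print.resistance_network <- function(x, ...) {
  cat(sprintf("<resistance_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  cat(sprintf("  confidence range: [%.3f, %.3f]; %d DEGs excluded (no qualifying edge)\n",
              min(x$edges$confidence), max(x$edges$confidence), length(x$excluded_degs)))
  invisible(x)
}

net_size <- function(net) nrow(net$nodes)

#' Write a resistance network as an edge-list TSV plus a JSON summary
#'
#' @param net A `resistance_network`.
#' @param path Output TSV path; a `<path>.json` summary is written alongside.
#' @export
write_network <- function(net, path) {
  write_table_checked(net$edges, path, "network edge list")
  summary <- list(nodes = nrow(net$nodes), edges = nrow(net$edges),
                  excluded_degs = length(net$excluded_degs))
  jsonlite::write_json(summary, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
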