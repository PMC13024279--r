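# Five raw node centralities. All functions return a numeric vector named by
# gene, in the node order of the network, raw (unnormalized): any per-metric
# affine normalization is absorbed by the Z-scoring downstream.

#' Degree centrality
#'
#' Raw edge count per node.
#'
#' @param net A `resistance_network` from [build_network()].
#' @return Named numeric vector in network node order.
#' @export
degree_centrality <- function(net) {
  d <- igraph::degree(net$graph, loops = FALSE)
  as.numeric(d) |> stats::setNames(names(d))
}

#' Betweenness centrality
#'
#' Unnormalized shortest-path betweenness on the unweighted graph (edge
#' confidences are ignored for path finding); each unordered pair is counted
#' once, the undirected convention.
#'
#' @inheritParams degree_centrality
#' @return Named numeric vector.
#' @export
betweenness_centrality <- function(net) {
  b <- igraph::betweenness(net$graph, directed = FALSE, weights = NA, normalized = FALSE)
  as.numeric(b) |> stats::setNames(names(b))
}

#' Eigenvector centrality
#'
#' Principal eigenvector of the binary adjacency matrix, L2-normalized with
#' all entries nonnegative, computed by power iteration. A unit diagonal
#' shift (A + I) is applied during iteration so the method also converges on
#' bipartite graphs, whose adjacency spectrum is symmetric; the shift leaves
#' the eigenvectors unchanged.
#'
#' @inheritParams degree_centrality
#' @param tol Convergence tolerance on the iterate (L2 change). Default 1e-10.
#' @param max_iter Maximum iterations before erroring. Default 10000.
#' @return Named numeric vector (unit L2 norm).
#' @export
eigenvector_centrality <- function(net, tol = 1e-10, max_iter = 10000) {
  A <- igraph::as_adjacency_matrix(net$graph, sparse = TRUE)
  A@x[] <- 1 # binary adjacency: ignore any weights
  n <- nrow(A)
  if (n == 1) return(stats::setNames(1, rownames(A)))
  x <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    y <- as.numeric(A %*% x) + x # (A + I) x
    y <- y / sqrt(sum(y^2))
    if (sqrt(sum((y - x)^2)) < tol) {
      return(stats::setNames(abs(y) / sqrt(sum(y^2)), rownames(A)))
    }
    x <- y
  }
  abort(sprintf("Eigenvector centrality did not converge in %d iterations; raise `max_iter`.", max_iter))
}

#' Maximal clique centrality (MCC)
#'
#' `MCC(v)` is the sum over all maximal cliques `C` containing `v` of
#' `(|C| - 1)!`. Maximal cliques are enumerated exactly (Bron-Kerbosch via
#' igraph). A node whose only maximal "cliques" are single edges gets its
#' degree, so `MCC(v) >= degree(v)` always.
#'
#' @inheritParams degree_centrality
#' @param clique_cap Safety cap on the number of maximal cliques; exceeding
#'   it raises an error (factorial blow-up guard). Default 1e6.
#' @return Named numeric vector of clique-factorial sums.
#' @export
mcc_centrality <- function(net, clique_cap = 1e6) {
  n_cl <- igraph::count_max_cliques(net$graph)
  if (n_cl > clique_cap) {
    abort(sprintf("Network has %d maximal cliques, above `clique_cap` = %g; raise the cap to proceed.",
                  n_cl, clique_cap))
  }
  cl <- igraph::max_cliques(net$graph)
  out <- stats::setNames(numeric(net_size(net)), net$nodes$gene)
  for (c in cl) {
    w <- factorial(length(c) - 1)
    nm <- names(c) %||% net$nodes$gene[as.integer(c)]
    out[nm] <- out[nm] + w
  }
  out
}

#' Edge percolated component (EPC)
#'
#' Monte-Carlo percolation over edge confidences: in realization `k` a
#' single threshold `t_k ~ Uniform(0, 1)` is drawn and every edge with
#' confidence strictly below `t_k` is deleted (so confidence-1 edges always
#' survive). `s_k(v)` is the number of nodes reachable from `v` (including
#' `v`, i.e. the size of its component) and
#' `EPC(v) = mean_k s_k(v) / |V|`. Deterministic given `seed`.
#'
#' @inheritParams degree_centrality
#' @param realizations Number of percolation realizations. Default 1000,
#'   the CytoHubba convention.
#' @param seed RNG seed; required for reproducibility.
#' @return Named numeric vector in `(0, 1]`.
#' @export
epc_centrality <- function(net, realizations = 1000, seed = NULL) {
  if (realizations < 1) abort("`realizations` must be >= 1.")
  check_seed(seed)
  g <- net$graph
  conf <- igraph::E(g)$confidence
  n <- net_size(net)
  acc <- numeric(n)
  with_seed(seed, {
    thresholds <- stats::runif(realizations)
    for (t_k in thresholds) {
      keep <- conf >= t_k
      sub <- igraph::subgraph_from_edges(g, which(keep), delete.vertices = FALSE)
      comp <- igraph::components(sub)
      acc <- acc + comp$csize[comp$membership]
    }
  })
  stats::setNames(acc / realizations / n, net$nodes$gene)
}

#' Compute all five centralities as a centrality matrix
#'
#' Runs degree, betweenness, eigenvector, MCC and EPC in the fixed metric
#' order and assembles them into a tibble with one row per node in network
#' node order.
#'
#' @inheritParams degree_centrality
#' @param epc_realizations Percolation realizations for EPC. Default 1000.
#' @param seed RNG seed for EPC.
#' @param tol,max_iter Passed to [eigenvector_centrality()].
#' @param clique_cap Passed to [mcc_centrality()].
#' @return A tibble of class `tihs_centrality` with columns `gene`,
#'   `degree`, `betweenness`, `eigenvector`, `mcc`, `epc`; attributes
#'   `epc_seed` and `epc_realizations`.
#' @export
compute_centralities <- function(net, epc_realizations = 1000, seed = NULL,
                                 tol = 1e-10, max_iter = 10000, clique_cap = 1e6) {
  cm <- tibble(
    gene = net$nodes$gene,
    degree = unname(degree_centrality(net)),
    betweenness = unname(betweenness_centrality(net)),
    eigenvector = unname(eigenvector_centrality(net, tol = tol, max_iter = max_iter)),
    mcc = unname(mcc_centrality(net, clique_cap = clique_cap)),
    epc = unname(epc_centrality(net, realizations = epc_realizations, seed = seed))
  )
  attr(cm, "epc_seed") <- seed
  attr(cm, "epc_realizations") <- epc_realizations
  class(cm) <- c("tihs_centrality", class(cm))
  cm
}

centrality_matrix <- function(cm) {
  m <- as.matrix(cm[, tihs_metrics()])
  rownames(m) <- cm$gene
  m
}
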