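# Fixture builders and independent brute-force oracles used across tests.

edge_tbl <- function(a, b, conf = 0.9) {
  tibble::tibble(node_a = a, node_b = b,
                 confidence = rep_len(conf, length(a)))
}

# Build a resistance_network directly from an edge tibble; every endpoint is
# treated as a DEG (log2fc defaults to 1).
toy_net <- function(edges, log2fc = NULL, min_confidence = 0,
                    restrict_to_lcc = FALSE) {
  genes <- sort(unique(c(edges$node_a, edges$node_b)))
  fc <- if (is.null(log2fc)) rep(1, length(genes)) else log2fc[genes]
  degs <- tibble::tibble(gene = genes, log2fc = unname(fc), padj = 0.01)
  suppressMessages(build_network(degs, edges,
                                 min_confidence = min_confidence,
                                 restrict_to_lcc = restrict_to_lcc))
}

# named adjacency matrix of a network, binary
net_adj <- function(net) {
  g <- sort(net$nodes$gene)
  A <- matrix(0L, length(g), length(g), dimnames = list(g, g))
  for (i in seq_len(nrow(net$edges))) {
    A[net$edges$node_a[i], net$edges$node_b[i]] <- 1L
    A[net$edges$node_b[i], net$edges$node_a[i]] <- 1L
  }
  A
}

# --- brute-force oracles (independent of igraph) ------------------------

# all-pairs BFS distances on an adjacency matrix
bf_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- integer(0)
      for (u in frontier) {
        for (v in which(A[u, ] == 1)) {
          if (D[s, v] > d) {
            D[s, v] <- d
            nxt <- c(nxt, v)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  D
}

# number of shortest paths between every pair (dynamic programming on the
# BFS distance levels)
bf_path_counts <- function(A, D) {
  n <- nrow(A)
  S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    S[s, s] <- 1
    for (t in order(D[s, ])) {
      if (t == s || !is.finite(D[s, t])) next
      preds <- which(A[, t] == 1 & D[s, ] == D[s, t] - 1)
      S[s, t] <- sum(S[s, preds])
    }
  }
  S
}

# unnormalized undirected betweenness, each unordered pair counted once
bf_betweenness <- function(A) {
  n <- nrow(A)
  D <- bf_distances(A)
  S <- bf_path_counts(A, D)
  out <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || !is.finite(D[s, t])) next
        if (D[s, v] + D[v, t] == D[s, t]) {
          out[v] <- out[v] + S[s, v] * S[v, t] / S[s, t]
        }
      }
    }
  }
  stats::setNames(out, rownames(A))
}

# exhaustive maximal-clique MCC over all vertex subsets (<= ~10 nodes)
bf_mcc <- function(A) {
  n <- nrow(A)
  out <- stats::setNames(numeric(n), rownames(A))
  subsets <- lapply(2:n, function(k) utils::combn(n, k, simplify = FALSE))
  subsets <- unlist(subsets, recursive = FALSE)
  is_clique <- function(s) all(A[s, s][upper.tri(diag(length(s)))] == 1)
  for (s in subsets) {
    if (!is_clique(s)) next
    extendable <- any(vapply(setdiff(seq_len(n), s),
                             function(v) all(A[v, s] == 1), logical(1)))
    if (!extendable) out[s] <- out[s] + factorial(length(s) - 1)
  }
  out
}

# random connected graph as an edge tibble (rejection sampling)
random_connected_edges <- function(n, p = 0.5) {
  repeat {
    pairs <- utils::combn(n, 2)
    keep <- stats::runif(ncol(pairs)) < p
    if (sum(keep) == 0) next
    A <- matrix(0L, n, n)
    for (k in which(keep)) A[pairs[1, k], pairs[2, k]] <- A[pairs[2, k], pairs[1, k]] <- 1L
    # connectivity check
    seen <- 1
    repeat {
      grow <- unique(c(seen, which(rowSums(A[, seen, drop = FALSE]) > 0)))
      if (length(grow) == length(seen)) break
      seen <- grow
    }
    if (length(seen) == n) {
      g <- sprintf("N%02d", seq_len(n))
      return(edge_tbl(g[pairs[1, keep]], g[pairs[2, keep]],
                      conf = stats::runif(sum(keep), 0.5, 1)))
    }
  }
}

# all labeled connected graphs on n nodes as edge tibbles (n <= 5)
all_connected_edge_sets <- function(n) {
  pairs <- utils::combn(n, 2)
  m <- ncol(pairs)
  g <- sprintf("N%02d", seq_len(n))
  out <- list()
  for (mask in seq_len(2^m - 1)) {
    keep <- bitwAnd(mask, 2^(seq_len(m) - 1)) > 0
    A <- matrix(0L, n, n)
    for (k in which(keep)) A[pairs[1, k], pairs[2, k]] <- A[pairs[2, k], pairs[1, k]] <- 1L
    seen <- 1
    repeat {
      grow <- unique(c(seen, which(rowSums(A[, seen, drop = FALSE]) > 0)))
      if (length(grow) == length(seen)) break
      seen <- grow
    }
    if (length(seen) == n) {
      out[[length(out) + 1]] <- edge_tbl(g[pairs[1, keep]], g[pairs[2, keep]], conf = 0.9)
    }
  }
  out
}

# tiny reusable synthetic study at reduced size for fast tests
small_sim <- function(seed = 1) {
  simulate_study(synthetic_config(n_genes = 120, n_hubs = 4, n_drugs = 24,
                                  n_planted_sensitive = 3, seed = seed))
}

filter_degs <- function(degs, fc_cutoff = 1, padj_cutoff = 0.05) {
  dplyr::filter(degs, abs(log2fc) >= fc_cutoff, padj < padj_cutoff)
}

run_quiet <- function(...) suppressMessages(suppressWarnings(run_tihs(...)))
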