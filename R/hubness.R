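# Normalization, metric weights, TIHS, and weight-vector stability.

#' Z-score and shift a centrality matrix
#'
#' Each metric column `j` is standardized with the population standard
#' deviation, `Z_ij = (X_ij - mu_j) / sigma_j`; degenerate columns
#' (`sigma_j = 0`) are set to all-zero Z. To make every entry strictly
#' positive each column is then shifted by its own minimum,
#' `Z'_ij = Z_ij - min_i(Z_ij) + 0.001`, so every shifted column has
#' minimum exactly 0.001.
#'
#' @param cm A `tihs_centrality` tibble from [compute_centralities()].
#' @return An object of class `tihs_normalized`: list with `genes`,
#'   `metrics`, `z` and `z_shifted` (genes x metrics matrices) and `stats`
#'   (tibble `metric`, `mu`, `sigma`, `min_z`).
#' @export
zscore_shift <- function(cm) {
  x <- centrality_matrix(cm)
  if (nrow(x) < 2) abort("Z-scoring needs at least 2 nodes.")
  mu <- colMeans(x)
  sigma <- sqrt(colMeans(sweep(x, 2, mu)^2)) # population sd
  z <- sweep(x, 2, mu)
  for (j in seq_along(sigma)) {
    z[, j] <- if (sigma[j] > 0) z[, j] / sigma[j] else 0
  }
  min_z <- apply(z, 2, min)
  zs <- sweep(z, 2, min_z) + 0.001
  structure(list(
    genes = rownames(x),
    metrics = colnames(x),
    z = z,
    z_shifted = zs,
    stats = tibble(metric = colnames(x), mu = unname(mu),
                   sigma = unname(sigma), min_z = unname(min_z))
  ), class = "tihs_normalized")
}

new_weights <- function(weight, metric, mode, source = NA_character_) {
  w <- tibble(metric = metric, weight = weight)
  attr(w, "mode") <- mode
  attr(w, "source") <- source
  class(w) <- c("tihs_weights", class(w))
  w
}

#' Derive per-metric weights from a centrality matrix
#'
#' Two modes:
#' \describe{
#'   \item{`std_share`}{each raw metric column is min-max rescaled to
#'     `[0, 1]` (making the shares unit-free), the population standard
#'     deviation `sigma_j` of the rescaled column is taken, and
#'     `W_j = sigma_j / sum_k sigma_k`. Degenerate columns get weight 0.}
#'   \item{`pca_loading`}{PCA of the Z-scored matrix (centered, unscaled;
#'     the columns are already standardized); `W_j` is the absolute PC1
#'     loading of metric `j`, normalized to sum 1. PC1 is sign-aligned so
#'     its largest-magnitude loading is positive.}
#' }
#'
#' @param nm A `tihs_normalized` object from [zscore_shift()].
#' @param cm The matching `tihs_centrality` tibble (raw values; used by
#'   `std_share`).
#' @param mode `"std_share"` (default) or `"pca_loading"`.
#' @param source Optional dataset label recorded on the result.
#' @return A `tihs_weights` tibble (`metric`, `weight`), weights on the
#'   probability simplex; attributes `mode`, `source`.
#' @export
derive_weights <- function(nm, cm, mode = c("std_share", "pca_loading"),
                           source = NA_character_) {
  mode <- match.arg(mode)
  if (length(nm$genes) < 2) abort("Weight derivation needs at least 2 nodes.")
  if (mode == "std_share") {
    x <- centrality_matrix(cm)
    sig <- apply(x, 2, function(col) {
      rng <- range(col)
      if (rng[2] == rng[1]) return(0)
      r <- (col - rng[1]) / (rng[2] - rng[1])
      sqrt(mean((r - mean(r))^2))
    })
    if (sum(sig) == 0) abort("All centrality columns are degenerate; no weights definable.")
    w <- sig / sum(sig)
  } else {
    keep <- nm$stats$sigma > 0
    if (!any(keep)) abort("All centrality columns are degenerate; no weights definable.")
    p <- stats::prcomp(nm$z[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
    load1 <- p$rotation[, 1]
    if (load1[which.max(abs(load1))] < 0) load1 <- -load1
    w <- stats::setNames(numeric(length(nm$metrics)), nm$metrics)
    w[keep] <- abs(load1) / sum(abs(load1))
  }
  new_weights(unname(w), nm$metrics, mode = mode, source = source)
}

check_weights <- function(w) {
  if (abs(sum(w$weight) - 1) > 1e-12) abort("Weights must sum to 1.")
  if (any(w$weight < 0)) abort("Weights must be nonnegative.")
  invisible(w)
}

#' Compute the Topology-Integrated Hubness Score
#'
#' `TIHS_i = sum_j W_j * Z'_ij` over the five shifted, standardized
#' centrality columns. Since weights are nonnegative, sum to 1 and every
#' `Z'` entry is positive, TIHS is strictly positive.
#'
#' @param nm A `tihs_normalized` object.
#' @param w A `tihs_weights` tibble over the same metrics.
#' @param cm Optional matching `tihs_centrality` tibble; when supplied the
#'   raw metric columns are carried into the output for reporting.
#' @return A tibble of class `tihs_hubness` with columns `gene`, optional
#'   raw metrics, `z_<metric>` shifted scores and `tihs`, sorted by TIHS
#'   descending (ties: gene ascending).
#' @export
compute_tihs <- function(nm, w, cm = NULL) {
  if (!setequal(nm$metrics, w$metric)) {
    abort(sprintf("Metric mismatch between matrix (%s) and weights (%s).",
                  paste(nm$metrics, collapse = ","), paste(w$metric, collapse = ",")))
  }
  check_weights(w)
  wv <- stats::setNames(w$weight, w$metric)[nm$metrics]
  tihs <- as.numeric(nm$z_shifted %*% wv)
  zs <- as_tibble(nm$z_shifted)
  names(zs) <- paste0("z_", nm$metrics)
  out <- dplyr::bind_cols(tibble(gene = nm$genes), zs, tibble(tihs = tihs))
  if (!is.null(cm)) {
    out <- dplyr::left_join(out, as_tibble(cm)[, c("gene", tihs_metrics())], by = "gene") |>
      dplyr::relocate(dplyr::all_of(tihs_metrics()), .after = "gene")
  }
  out <- dplyr::arrange(out, dplyr::desc(.data$tihs), .data$gene)
  class(out) <- c("tihs_hubness", class(out))
  out
}

#' Average several weight vectors into a unified vector
#'
#' Arithmetic mean per metric, renormalized to sum exactly 1. Mixing
#' derivation modes triggers a warning, not an error.
#'
#' @param vectors A list of `tihs_weights` tibbles over identical metrics.
#' @return A `tihs_weights` tibble with mode of the inputs (or "mixed").
#' @export
average_weights <- function(vectors) {
  if (length(vectors) < 1) abort("Need at least one weight vector.")
  metrics <- vectors[[1]]$metric
  for (v in vectors) {
    if (!identical(v$metric, metrics)) abort("Weight vectors have differing metric sets/order.")
  }
  modes <- unique(vapply(vectors, function(v) attr(v, "mode") %||% "unknown", ""))
  if (length(modes) > 1) {
    warn(sprintf("Averaging weight vectors of mixed modes: %s", paste(modes, collapse = ", ")))
  }
  m <- rowMeans(vapply(vectors, function(v) v$weight, numeric(length(metrics))))
  new_weights(m / sum(m), metrics, mode = if (length(modes) == 1) modes else "mixed",
              source = "averaged")
}

#' Cross-dataset stability of weight vectors
#'
#' Cosine similarity (on unit-normalized vectors) and Pearson correlation of
#' each dataset-specific weight vector against the unified vector, with a
#' stability flag at `threshold` (default 0.98).
#'
#' @param vectors Named list of `tihs_weights` tibbles.
#' @param unified The unified (averaged) `tihs_weights` vector.
#' @param threshold Cosine flagging threshold. Default 0.98.
#' @return A tibble of class `tihs_stability`: `source`, `cosine`,
#'   `pearson`, `stable`.
#' @export
cosine_stability <- function(vectors, unified, threshold = 0.98) {
  u <- unified$weight
  if (sqrt(sum(u^2)) == 0) abort("Unified weight vector has zero norm.")
  nm <- names(vectors) %||% paste0("dataset", seq_along(vectors))
  rows <- purrr::imap(vectors, function(v, label) {
    if (!identical(v$metric, unified$metric)) abort("Metric sets differ from the unified vector.")
    x <- v$weight
    if (sqrt(sum(x^2)) == 0) abort(sprintf("Weight vector '%s' has zero norm.", label))
    tibble(source = label,
           cosine = sum(x * u) / (sqrt(sum(x^2)) * sqrt(sum(u^2))),
           pearson = stats::cor(x, u))
  })
  out <- purrr::list_rbind(rows) |>
    dplyr::mutate(stable = .data$cosine >= threshold)
  attr(out, "threshold") <- threshold
  class(out) <- c("tihs_stability", class(out))
  out
}
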