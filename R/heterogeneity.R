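# Resistance-shift heterogeneity: genes x models log2FC matrix, model-level
# PCA, pairwise Pearson, complete-linkage clustering, gene-level bootstrap.

#' Build a genes x models resistance-shift matrix
#'
#' Rows are the genes shared by every model (intersection, no imputation),
#' sorted alphabetically; columns are the models' log2 fold changes
#' (resistant vs parental).
#'
#' @param deg_tables Named list of DEG tibbles (columns `gene`, `log2fc`);
#'   typically unthresholded tables so the intersection is large.
#' @return Object of class `shift_matrix`: list with `genes`, `models`,
#'   `values` (genes x models matrix) and a `tbl` tibble view.
#' @export
build_shift_matrix <- function(deg_tables) {
  if (length(deg_tables) < 2) abort("Need at least 2 models.")
  models <- names(deg_tables) %||% paste0("model", seq_along(deg_tables))
  tabs <- purrr::map(deg_tables, function(d) {
    assert_cols(d, c("gene", "log2fc"), "DEG table")
    dedup_degs(dplyr::mutate(d, gene = norm_gene(.data$gene)))
  })
  genes <- Reduce(intersect, purrr::map(tabs, "gene"))
  if (length(genes) == 0) abort("Empty gene intersection across models.")
  genes <- sort(genes)
  values <- vapply(tabs, function(d) d$log2fc[match(genes, d$gene)],
                   numeric(length(genes)))
  colnames(values) <- models
  rownames(values) <- genes
  structure(list(genes = genes, models = models, values = values,
                 tbl = dplyr::bind_cols(tibble(gene = genes), as_tibble(values))),
            class = "shift_matrix")
}

#' @export
print.shift_matrix <- function(x, ...) {
  cat(sprintf("<shift_matrix> %d shared genes x %d models (%s)\n",
              length(x$genes), length(x$models), paste(x$models, collapse = ", ")))
  invisible(x)
}

# Sign convention: orient each PC so its largest-|loading| variable is
# positive (pins the eigenvector sign ambiguity).
align_pc_signs <- function(p) {
  for (k in seq_len(ncol(p$rotation))) {
    if (p$rotation[which.max(abs(p$rotation[, k])), k] < 0) {
      p$rotation[, k] <- -p$rotation[, k]
      p$x[, k] <- -p$x[, k]
    }
  }
  p
}

#' PCA of models in resistance-shift space
#'
#' Observations are the models, variables the shared genes; columns are
#' centered but not scaled. PCs are sign-aligned so the largest-magnitude
#' loading on each PC is positive.
#'
#' @param m A `shift_matrix`.
#' @return Object of class `tihs_pca`: list with `coords` (tibble `model`,
#'   `PC1`, ...), `var_explained` (fractions summing to 1) and the
#'   underlying `prcomp` fit.
#' @export
pca_models <- function(m) {
  p <- stats::prcomp(t(m$values), center = TRUE, scale. = FALSE)
  p <- align_pc_signs(p)
  ve <- p$sdev^2 / sum(p$sdev^2)
  coords <- dplyr::bind_cols(tibble(model = m$models), as_tibble(p$x))
  structure(list(coords = coords, var_explained = ve, fit = p),
            class = "tihs_pca")
}

#' Pairwise Pearson correlation of model shift vectors
#'
#' @param m A `shift_matrix` with at least 3 genes.
#' @return Symmetric models x models correlation matrix with unit diagonal;
#'   zero-variance models produce `NA` entries with a warning.
#' @export
pairwise_pearson <- function(m) {
  if (length(m$genes) < 3) abort("Need at least 3 genes for correlations.")
  zero_var <- apply(m$values, 2, stats::sd) == 0
  if (any(zero_var)) {
    warn(sprintf("Model(s) with zero variance: %s; correlations reported as NA.",
                 paste(m$models[zero_var], collapse = ", ")))
  }
  suppressWarnings(stats::cor(m$values))
}

#' Complete-linkage clustering of models on correlation distance
#'
#' Distance is `1 - r`; linkage is complete. Returns a base `hclust`
#' object (merge list with heights), which [stats::as.dendrogram()] or
#' `ape::as.phylo()` can consume.
#'
#' @param corr A models x models correlation matrix.
#' @return An `hclust` object.
#' @export
cluster_models <- function(corr) {
  if (anyNA(corr)) abort("Correlation matrix contains NA; cannot cluster.")
  stats::hclust(stats::as.dist(1 - corr), method = "complete")
}

#' Gene-level bootstrap of the model PCA embedding
#'
#' Each iteration resamples genes (rows) with replacement, recomputes the
#' model PCA, and aligns per-PC signs to the reference embedding (sign
#' chosen to maximize correlation with the reference coordinates), so
#' eigenvector sign flips do not scramble the coordinate clouds.
#'
#' @param m A `shift_matrix`.
#' @param iterations Bootstrap iterations (>= 10). Default 500.
#' @param seed RNG seed.
#' @param n_pcs Number of PCs to retain. Default 2.
#' @return Tibble `iteration`, `model`, `PC1`, ... (the coordinate clouds).
#' @export
bootstrap_pca <- function(m, iterations = 500, seed = NULL, n_pcs = 2) {
  if (iterations < 10) abort("Use at least 10 bootstrap iterations.")
  check_seed(seed)
  ref <- pca_models(m)
  n_pcs <- min(n_pcs, ncol(ref$fit$x))
  ref_x <- ref$fit$x[, seq_len(n_pcs), drop = FALSE]
  n_genes <- length(m$genes)
  clouds <- with_seed(seed, {
    purrr::map(seq_len(iterations), function(it) {
      idx <- sample.int(n_genes, n_genes, replace = TRUE)
      vals <- m$values[idx, , drop = FALSE]
      p <- stats::prcomp(t(vals), center = TRUE, scale. = FALSE)
      x <- p$x[, seq_len(min(n_pcs, ncol(p$x))), drop = FALSE]
      for (k in seq_len(ncol(x))) {
        if (sum(x[, k] * ref_x[, k]) < 0) x[, k] <- -x[, k]
      }
      out <- matrix(0, nrow = length(m$models), ncol = n_pcs,
                    dimnames = list(NULL, paste0("PC", seq_len(n_pcs))))
      out[, seq_len(ncol(x))] <- x
      dplyr::bind_cols(tibble(iteration = it, model = m$models), as_tibble(out))
    })
  })
  purrr::list_rbind(clouds)
}
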