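# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_hline
#'   geom_segment coord_polar labs theme_minimal ylim
#' @export
ggplot2::autoplot

#' Plot the top hub genes of a hubness table
#'
#' @param object A `tihs_hubness` tibble from [compute_tihs()].
#' @param n_top Number of top-TIHS genes to show. Default 20.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tihs_hubness
#' @export
autoplot.tihs_hubness <- function(object, n_top = 20, ...) {
  df <- utils::head(dplyr::arrange(object, dplyr::desc(.data$tihs)), n_top)
  ggplot(df, aes(x = stats::reorder(.data$gene, .data$tihs), y = .data$tihs)) +
    geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    labs(x = NULL, y = "TIHS", title = sprintf("Top %d hub genes", nrow(df))) +
    theme_minimal()
}

#' Plot drug sensitivity scores with tier-1 status
#'
#' @param object A ranked (and optionally filtered) drug tibble from
#'   [rank_drugs()] / [apply_filters()].
#' @param n_top Number of top-ranked drugs to show. Default 25.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tihs_ranking
#' @export
autoplot.tihs_ranking <- function(object, n_top = 25, ...) {
  df <- utils::head(dplyr::arrange(object, .data$rank), n_top)
  fill <- if ("tier1_pass" %in% names(df)) df$tier1_pass else df$sensitivity_score > 0
  ggplot(df, aes(x = stats::reorder(.data$drug_name, -.data$rank),
                 y = .data$sensitivity_score)) +
    geom_col(aes(fill = fill)) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey60"),
                               name = "tier 1") +
    ggplot2::coord_flip() +
    labs(x = NULL, y = "drug sensitivity score") +
    theme_minimal()
}

#' Polar stability plot of weight-vector cosine similarities
#'
#' One spoke per dataset, with a dashed ring at the stability threshold
#' (default 0.98).
#'
#' @param object A `tihs_stability` tibble from [cosine_stability()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tihs_stability
#' @export
autoplot.tihs_stability <- function(object, ...) {
  thr <- attr(object, "threshold") %||% 0.98
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$source, y = .data$cosine)) +
    geom_segment(aes(xend = .data$source, y = 0, yend = .data$cosine),
                 colour = "grey70") +
    geom_point(aes(colour = .data$stable), size = 3) +
    geom_hline(yintercept = thr, linetype = "dashed", colour = "firebrick") +
    coord_polar() +
    ylim(0, 1) +
    labs(y = "cosine similarity to unified weights", x = NULL) +
    theme_minimal()
}

#' Plot bootstrap coordinate clouds of the model PCA
#'
#' @param clouds Tibble from [bootstrap_pca()].
#' @param reference Optional `tihs_pca` reference embedding to overlay.
#' @return A ggplot.
#' @export
plot_bootstrap_pca <- function(clouds, reference = NULL) {
  p <- ggplot(clouds, aes(x = .data$PC1, y = .data$PC2, colour = .data$model)) +
    geom_point(alpha = 0.25, size = 0.8) +
    labs(title = "Gene-level bootstrap of the model embedding") +
    theme_minimal()
  if (!is.null(reference)) {
    p <- p + geom_point(data = reference$coords, size = 3, shape = 4, stroke = 1.5)
  }
  p
}
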