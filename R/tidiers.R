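# broom-style tidiers.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a TIHS pipeline result
#'
#' One row per ranked drug, with scores, ranks and tier flags.
#'
#' @param x A `tihs_result` from [run_tihs()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy tihs_result
#' @export
tidy.tihs_result <- function(x, ...) {
  out <- as_tibble(x$ranked)
  out$matched_targets <- NULL
  class(out) <- class(tibble())
  out
}

#' @rdname tidy.tihs_result
#' @method glance tihs_result
#' @export
glance.tihs_result <- function(x, ...) {
  tibble(
    n_nodes = unname(x$counts[["nodes"]]),
    n_edges = unname(x$counts[["edges"]]),
    n_drugs = unname(x$counts[["drugs_scored"]]),
    n_tier1 = unname(x$counts[["tier1"]]),
    n_pass_all = unname(x$counts[["pass_all"]]),
    weights_mode = attr(x$weights, "mode")
  )
}

#' Tidy a weight-stability report
#'
#' @param x A `tihs_stability` tibble from [cosine_stability()].
#' @param ... Unused.
#' @return A plain tibble.
#' @method tidy tihs_stability
#' @export
tidy.tihs_stability <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' Tidy a model-level PCA of the resistance-shift matrix
#'
#' @param x A `tihs_pca` from [pca_models()].
#' @param ... Unused.
#' @return Tibble of model coordinates in PC space.
#' @method tidy tihs_pca
#' @export
tidy.tihs_pca <- function(x, ...) x$coords

#' @rdname tidy.tihs_pca
#' @method glance tihs_pca
#' @export
glance.tihs_pca <- function(x, ...) {
  tibble(pc = paste0("PC", seq_along(x$var_explained)),
         var_explained = x$var_explained) |>
    tidyr::pivot_wider(names_from = "pc", values_from = "var_explained")
}

#' Tidy a validation report
#'
#' @param x A `tihs_validation` from [validate_predictions()].
#' @param ... Unused.
#' @return The per-drug tibble with direct and permutation p-values.
#' @method tidy tihs_validation
#' @export
tidy.tihs_validation <- function(x, ...) x$per_drug

#' @rdname tidy.tihs_validation
#' @method glance tihs_validation
#' @export
glance.tihs_validation <- function(x, ...) x$summary
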