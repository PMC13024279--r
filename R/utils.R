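# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer pivot_wider
#' @importFrom purrr map map_dbl map_int map2 imap list_rbind
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

check_seed <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
      abort("`seed` must be a single finite number or NULL.")
    }
  }
  seed
}

# Canonical metric order used everywhere downstream.
tihs_metrics <- function() c("degree", "betweenness", "eigenvector", "mcc", "epc")

norm_gene <- function(x) toupper(trimws(as.character(x)))

# Format numerics at 6 significant digits for TSV output.
fmt_num <- function(x) formatC(x, digits = 6, format = "g")

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s (found: %s)",
      what, paste(missing, collapse = ", "), paste(names(df), collapse = ", ")
    ))
  }
  invisible(df)
}
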