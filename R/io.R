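#' Read a differential-expression table and apply DEG thresholds
#'
#' Reads a TSV of per-gene differential-expression results (as produced by
#' DESeq2, limma, edgeR, ...) and keeps the differentially expressed genes:
#' rows with `|log2fc| >= fc_cutoff` (inclusive) and `padj < padj_cutoff`
#' (strict). Header names are configurable because DE tools differ.
#'
#' Duplicate gene symbols are collapsed to a single record, keeping the row
#' with maximum `|log2fc|` (ties: smaller `padj`, then first occurrence), so
#' the strongest resistance signal per gene is preserved.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param fc_cutoff Minimum absolute log2 fold change (inclusive). Default 1.
#' @param padj_cutoff Adjusted p-value bound (strict `<`). Default 0.05.
#' @param col_gene,col_log2fc,col_padj,col_base Column names in the file.
#'   `col_base` (mean normalized expression) is optional in the file.
#' @return A tibble with columns `gene`, `log2fc`, `padj`, `base_expr`
#'   (`NA` when absent), one row per retained gene, symbols upper-cased.
#'   Attribute `counts` records rows read / filtered / deduplicated.
#' @export
read_deg_table <- function(path, fc_cutoff = 1, padj_cutoff = 0.05,
                           col_gene = "gene", col_log2fc = "log2FoldChange",
                           col_padj = "padj", col_base = "baseMean") {
  if (!file.exists(path)) abort(sprintf("DEG table not found: %s", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()))
  assert_cols(raw, c(col_gene, col_log2fc, col_padj), sprintf("DEG table '%s'", path))
  df <- tibble(
    gene = norm_gene(raw[[col_gene]]),
    log2fc = parse_num_col(raw[[col_log2fc]], col_log2fc, path),
    padj = parse_num_col(raw[[col_padj]], col_padj, path),
    base_expr = if (col_base %in% names(raw)) {
      parse_num_col(raw[[col_base]], col_base, path)
    } else {
      NA_real_
    }
  )
  n_read <- nrow(df)
  df <- dplyr::filter(df, .data$gene != "", is.finite(.data$log2fc), is.finite(.data$padj))
  bad_padj <- df$padj < 0 | df$padj > 1
  if (any(bad_padj)) {
    abort(sprintf("DEG table '%s': %d padj value(s) outside [0, 1].", path, sum(bad_padj)))
  }
  df <- dplyr::filter(df, abs(.data$log2fc) >= fc_cutoff, .data$padj < padj_cutoff)
  n_pass <- nrow(df)
  df <- dedup_degs(df)
  inform(sprintf("DEG table: %d rows read, %d pass |log2FC| >= %g & padj < %g, %d unique genes.",
                 n_read, n_pass, fc_cutoff, padj_cutoff, nrow(df)))
  attr(df, "counts") <- c(read = n_read, pass = n_pass, unique = nrow(df))
  df
}

parse_num_col <- function(x, name, path) {
  if (is.numeric(x)) return(as.numeric(x))
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "NA" & is.na(out))
  if (length(bad) > 0) {
    abort(sprintf("Column '%s' in '%s': unparseable numeric at data row(s) %s (e.g. \"%s\").",
                  name, path, paste(utils::head(bad, 5), collapse = ", "), x[bad[1]]))
  }
  out
}

dedup_degs <- function(df) {
  df |>
    dplyr::mutate(.ord = dplyr::row_number()) |>
    dplyr::arrange(.data$gene, dplyr::desc(abs(.data$log2fc)), .data$padj, .data$.ord) |>
    dplyr::distinct(.data$gene, .keep_all = TRUE) |>
    dplyr::arrange(.data$.ord) |>
    dplyr::select(-".ord")
}

#' Read a protein-interaction link file into a gene-symbol edge list
#'
#' Supports two dialects, auto-detected: the STRING `protein_links` format
#' (whitespace-delimited `protein1 protein2 combined_score` with integer
#' scores 0-999, divided by 1000 on read) and a pre-mapped TSV
#' `gene_a gene_b confidence` with confidence already in `[0, 1]`. A file
#' whose scores all lie in `[0, 1]` is never rescaled.
#'
#' When `mapping_path` is supplied, protein identifiers are translated to
#' gene symbols (`protein_id<TAB>gene_symbol`); edges with an unmapped
#' endpoint are dropped and counted. Reciprocal/duplicate edges are merged
#' keeping the maximum confidence; self-loops are removed.
#'
#' @param path Edge-list file (whitespace- or tab-delimited, with or without
#'   a header line).
#' @param mapping_path Optional protein-to-symbol mapping TSV.
#' @param min_confidence Minimum retained edge confidence (inclusive).
#'   Default 0.7, the conventional high-confidence STRING cutoff.
#' @return A tibble `node_a`, `node_b`, `confidence` with `node_a < node_b`,
#'   symbols upper-cased; attribute `counts` records read/mapped/retained.
#' @export
read_string_links <- function(path, mapping_path = NULL, min_confidence = 0.7) {
  if (!file.exists(path)) abort(sprintf("Link file not found: %s", path))
  raw <- utils::read.table(path, header = detect_header(path), stringsAsFactors = FALSE)
  if (ncol(raw) < 3) abort(sprintf("Link file '%s' needs 3 columns (two ids and a score).", path))
  ed <- tibble(
    node_a = as.character(raw[[1]]),
    node_b = as.character(raw[[2]]),
    confidence = parse_num_col(raw[[3]], "score", path)
  )
  n_read <- nrow(ed)
  # STRING dialect: integer combined scores on the 0-999 scale.
  if (any(ed$confidence > 1, na.rm = TRUE)) {
    ed$confidence <- ed$confidence / 1000
  }
  if (any(ed$confidence < 0 | ed$confidence > 1, na.rm = TRUE)) {
    abort(sprintf("Link file '%s': confidences outside [0, 1] after scale detection.", path))
  }
  n_unmapped <- 0L
  if (!is.null(mapping_path)) {
    map <- utils::read.table(mapping_path, header = detect_header(mapping_path),
                             stringsAsFactors = FALSE)
    if (ncol(map) < 2) abort(sprintf("Mapping file '%s' needs 2 columns.", mapping_path))
    lut <- stats::setNames(norm_gene(map[[2]]), as.character(map[[1]]))
    a <- unname(lut[ed$node_a])
    b <- unname(lut[ed$node_b])
    keep <- !is.na(a) & !is.na(b)
    n_unmapped <- sum(!keep)
    if (!any(keep)) {
      abort(sprintf("Mapping '%s' covers 0 of %d edges; wrong mapping file?", mapping_path, n_read))
    }
    ed <- tibble(node_a = a[keep], node_b = b[keep], confidence = ed$confidence[keep])
  }
  ed$node_a <- norm_gene(ed$node_a)
  ed$node_b <- norm_gene(ed$node_b)
  ed <- merge_edges(ed)
  ed <- dplyr::filter(ed, .data$confidence >= min_confidence)
  inform(sprintf("Links: %d read, %d dropped unmapped, %d unique edges >= %g.",
                 n_read, n_unmapped, nrow(ed), min_confidence))
  attr(ed, "counts") <- c(read = n_read, unmapped = n_unmapped, retained = nrow(ed))
  ed
}

detect_header <- function(path) {
  first <- readLines(path, n = 1)
  fields <- strsplit(trimws(first), "[ \t]+")[[1]]
  length(fields) >= 3 && is.na(suppressWarnings(as.numeric(fields[3])))
}

# Canonicalize undirected edges: drop self-loops, order endpoints, merge
# parallel/reciprocal edges keeping the maximum confidence.
merge_edges <- function(ed) {
  ed <- dplyr::filter(ed, .data$node_a != .data$node_b)
  swap <- ed$node_a > ed$node_b
  tmp <- ed$node_a[swap]
  ed$node_a[swap] <- ed$node_b[swap]
  ed$node_b[swap] <- tmp
  ed |>
    dplyr::group_by(.data$node_a, .data$node_b) |>
    dplyr::summarise(confidence = max(.data$confidence), .groups = "drop") |>
    dplyr::arrange(.data$node_a, .data$node_b)
}

#' Read a curated drug-target activity table
#'
#' Expects a TSV with columns `drug_id`, `drug_name`, `target_gene`,
#' `activity_value`, `activity_unit`, `activity_type`, `mechanism` (a
#' ChEMBL-style flat export). Activities are converted to nM; supported
#' units are nM, uM (also spelled \eqn{\mu}M) and M, case-insensitive.
#' Nonpositive or missing activities are dropped with a warning count.
#'
#' @param path Path to the TSV.
#' @return Tibble `drug_id`, `drug_name`, `target_gene`, `activity_nm`,
#'   `activity_type`, `mechanism`; attribute `counts`.
#' @export
read_drug_target_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("Drug-target table not found: %s", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_cols(raw, c("drug_id", "drug_name", "target_gene", "activity_value",
                     "activity_unit", "activity_type", "mechanism"),
              sprintf("drug-target table '%s'", path))
  unit <- tolower(trimws(raw$activity_unit))
  factor <- c(nm = 1, um = 1e3, "µm" = 1e3, m = 1e9)[unit]
  if (anyNA(factor)) {
    bad <- which(is.na(factor))
    abort(sprintf(
      "Drug-target table '%s': unknown activity unit \"%s\" at data row %d; supported units: nM, uM, M.",
      path, raw$activity_unit[bad[1]], bad[1]))
  }
  df <- tibble(
    drug_id = as.character(raw$drug_id),
    drug_name = as.character(raw$drug_name),
    target_gene = norm_gene(raw$target_gene),
    activity_nm = parse_num_col(raw$activity_value, "activity_value", path) * unname(factor),
    activity_type = as.character(raw$activity_type),
    mechanism = as.character(raw$mechanism)
  )
  n_read <- nrow(df)
  ok <- is.finite(df$activity_nm) & df$activity_nm > 0
  if (any(!ok)) {
    warn(sprintf("Drug-target table '%s': dropped %d record(s) with nonpositive or missing activity.",
                 path, sum(!ok)))
  }
  df <- df[ok, ]
  attr(df, "counts") <- c(read = n_read, dropped = n_read - nrow(df), retained = nrow(df))
  df
}

#' Read a Cmax (maximum plasma concentration) table
#'
#' @param path TSV with columns `drug_id`, `cmax_nm` (nM, positive).
#' @return Tibble `drug_id`, `cmax_nm`.
#' @export
read_cmax_table <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_cols(raw, c("drug_id", "cmax_nm"), sprintf("Cmax table '%s'", path))
  df <- tibble(drug_id = as.character(raw$drug_id),
               cmax_nm = parse_num_col(raw$cmax_nm, "cmax_nm", path))
  if (any(!is.finite(df$cmax_nm) | df$cmax_nm <= 0)) {
    abort(sprintf("Cmax table '%s': cmax_nm must be positive.", path))
  }
  df
}

#' Read a curated drug-phenotype validation pair table
#'
#' Each row records, for one dataset/cell-line/drug triple, the literature
#' ground-truth effect in the resistant state, the predicted effect, and the
#' drug's rank among all evaluated candidates.
#'
#' @param path TSV with columns `dataset`, `context`, `drug_name`,
#'   `actual_effect` (sensitive/resistant), `predicted_effect`
#'   (sensitive/resistant/not_observed), `rank_obs`, `n_cand` (both may be NA).
#' @return Tibble of validation pairs with a logical `correct` column.
#' @export
read_validation_pairs <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA"))
  assert_cols(raw, c("dataset", "context", "drug_name", "actual_effect",
                     "predicted_effect", "rank_obs", "n_cand"),
              sprintf("validation pair table '%s'", path))
  df <- tibble(
    dataset = as.character(raw$dataset),
    context = as.character(raw$context),
    drug_name = as.character(raw$drug_name),
    actual_effect = tolower(as.character(raw$actual_effect)),
    predicted_effect = tolower(as.character(raw$predicted_effect)),
    rank_obs = as.integer(raw$rank_obs),
    n_cand = as.integer(raw$n_cand)
  )
  if (!all(df$actual_effect %in% c("sensitive", "resistant"))) {
    abort("actual_effect must be 'sensitive' or 'resistant'.")
  }
  if (!all(df$predicted_effect %in% c("sensitive", "resistant", "not_observed"))) {
    abort("predicted_effect must be 'sensitive', 'resistant' or 'not_observed'.")
  }
  both <- !is.na(df$rank_obs) & !is.na(df$n_cand)
  if (any(both & df$rank_obs > df$n_cand)) abort("rank_obs must be <= n_cand.")
  df$correct <- df$predicted_effect == df$actual_effect
  df
}

#' The bundled curated drug-phenotype validation pairs
#'
#' Twelve literature-supported drug-phenotype pairs across four public
#' resistance cohorts (gefitinib-, tamoxifen- and palbociclib/fulvestrant-
#' resistance models), with the observed rank of each drug among all
#' evaluated candidates where the drug was recovered by the scoring.
#'
#' @return Tibble as from [read_validation_pairs()].
#' @export
curated_validation_pairs <- function() {
  read_validation_pairs(system.file("extdata", "validation_pairs.tsv",
                                    package = "tihs", mustWork = TRUE))
}

write_table_checked <- function(df, path, what) {
  if (is.null(df) || nrow(df) == 0) abort(sprintf("Refusing to write empty %s to '%s'.", what, path))
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  out <- df
  out[num] <- lapply(df[num], fmt_num)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a hubness table to TSV
#'
#' Columns: `gene`, the five raw centralities, the five shifted Z-scores
#' (`z_degree`, ...) and `tihs`; rows ordered by TIHS descending then gene
#' ascending; floats at 6 significant digits.
#'
#' @param hub A hubness table from [compute_tihs()].
#' @param path Output path.
#' @export
write_hubness_table <- function(hub, path) {
  write_table_checked(
    dplyr::arrange(hub, dplyr::desc(.data$tihs), .data$gene), path, "hubness table")
}

#' Write a ranked drug table to TSV
#'
#' @param ranked Output of [rank_drugs()] or [apply_filters()].
#' @param path Output path.
#' @export
write_ranked_drugs <- function(ranked, path) {
  df <- ranked
  if ("matched_targets" %in% names(df)) df$matched_targets <- NULL
  df <- dplyr::arrange(df, dplyr::desc(.data$sensitivity_score), .data$drug_name)
  write_table_checked(df, path, "ranked drug table")
}

#' Write a metric weight vector as key-value text
#'
#' @param w A weight vector from [derive_weights()] or [average_weights()].
#' @param path Output path.
#' @export
write_weight_vector <- function(w, path) {
  if (is.null(w) || nrow(w) == 0) abort(sprintf("Refusing to write empty weight vector to '%s'.", path))
  lines <- c(sprintf("# mode: %s", attr(w, "mode") %||% "unknown"),
             sprintf("%s\t%s", w$metric, fmt_num(w$weight)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a weight vector written by [write_weight_vector()]
#'
#' @param path Path to the key-value text file.
#' @return A weight tibble (`metric`, `weight`) with attribute `mode`.
#' @export
read_weight_vector <- function(path) {
  lines <- readLines(path)
  mode <- sub("^# mode: ", "", lines[startsWith(lines, "# mode:")][1])
  lines <- lines[!startsWith(lines, "#")]
  parts <- strsplit(lines, "\t")
  w <- tibble(metric = vapply(parts, `[[`, "", 1),
              weight = as.numeric(vapply(parts, `[[`, "", 2)))
  new_weights(w$weight, w$metric, mode = if (is.na(mode)) "unknown" else mode)
}
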