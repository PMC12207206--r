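# Single-cell pseudobulk aggregation and per-cell-type signature profiles.

#' Aggregate single-cell counts into per-(patient, cell type) pseudobulk
#'
#' Each pseudobulk column is the element-wise sum of its member cells'
#' counts. Cells lacking a patient or cell-type label are excluded and
#' counted in the report; columns built from fewer than `min_cells` cells
#' are flagged (not dropped).
#'
#' @param cell_counts gene-by-cell count matrix (dense or sparse); column
#'   names are cell ids.
#' @param cell_meta data.frame with columns `cell_id`, `patient_id`,
#'   `cell_type`.
#' @param min_cells flag threshold for small columns.
#' @return list: `counts` (gene-by-pseudobulk integer matrix, columns named
#'   `patient|cell_type`), `meta` (data.frame column, patient_id, cell_type,
#'   n_cells, flagged), `n_excluded`.
#' @export
pseudobulk_aggregate <- function(cell_counts, cell_meta, min_cells = 10) {
  meta <- cell_meta[match(colnames(cell_counts), cell_meta$cell_id), ,
                    drop = FALSE]
  ok <- !is.na(meta$patient_id) & !is.na(meta$cell_type) &
    !is.na(meta$cell_id)
  n_excluded <- sum(!ok)
  m <- cell_counts[, ok, drop = FALSE]
  meta <- meta[ok, , drop = FALSE]
  key <- paste(meta$patient_id, meta$cell_type, sep = "|")
  ukey <- sort(unique(key))
  ind <- Matrix::sparseMatrix(i = seq_along(key),
                              j = match(key, ukey),
                              x = 1, dims = c(length(key), length(ukey)))
  agg <- as.matrix(m %*% ind)
  dimnames(agg) <- list(rownames(cell_counts), ukey)
  storage.mode(agg) <- "integer"
  ncells <- as.integer(table(factor(key, levels = ukey)))
  parts <- strsplit(ukey, "|", fixed = TRUE)
  pb_meta <- data.frame(
    column = ukey,
    patient_id = vapply(parts, `[`, character(1), 1),
    cell_type = vapply(parts, `[`, character(1), 2),
    n_cells = ncells,
    flagged = ncells < min_cells,
    stringsAsFactors = FALSE)
  list(counts = agg, meta = pb_meta, n_excluded = n_excluded)
}

#' Per-cell-type signature profile over a pseudobulk matrix
#'
#' TMM-normalizes the pseudobulk columns, computes log2 CPM, scores the
#' signature per (patient, cell type), and summarizes each cell type by its
#' median score and rank (1 = highest).
#'
#' @param pb result of [pseudobulk_aggregate] (or a compatible list with
#'   `counts` and `meta`).
#' @param signature character vector of gene symbols.
#' @param sig_name label for error messages.
#' @return list: `scores` (data.frame patient_id, cell_type, score),
#'   `summary` (data.frame cell_type, median_score, rank, n).
#' @export
celltype_signature_profile <- function(pb, signature,
                                       sig_name = "signature") {
  norm <- normalize_counts(pb$counts)
  sc <- signature_score(norm, signature, sig_name = sig_name)
  scores <- data.frame(patient_id = pb$meta$patient_id,
                       cell_type = pb$meta$cell_type,
                       score = as.numeric(sc[pb$meta$column]),
                       stringsAsFactors = FALSE)
  med <- tapply(scores$score, scores$cell_type, stats::median)
  summary <- data.frame(cell_type = names(med),
                        median_score = as.numeric(med),
                        n = as.integer(table(scores$cell_type)[names(med)]),
                        stringsAsFactors = FALSE)
  summary <- summary[order(-summary$median_score), , drop = FALSE]
  summary$rank <- seq_len(nrow(summary))
  rownames(summary) <- NULL
  list(scores = scores, summary = summary,
       n_genes_used = attr(sc, "n_genes_used"))
}
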