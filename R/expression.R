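# CDS-restricted counts to TPM and log2(TPM+1). TPM uses the CDS length of
# each gene (counting was CDS-restricted upstream) so per-kilobase rates and
# the per-cell normalization to one million are internally consistent.

#' Convert a count matrix to TPM and log2(TPM+1)
#'
#' Per cell: `rate_g = count_g / (cds_length_bp_g / 1000)` and
#' `tpm_g = rate_g / sum(rate) * 1e6`. Every non-degenerate cell column of
#' TPM therefore sums to 1e6. All-zero cells are retained as all-zero
#' columns with a warning (dropping low-quality cells is the QC stage's
#' job, not the normalizer's).
#'
#' @param counts gene x cell non-negative matrix with dimnames, or a
#'   `sim_dataset`.
#' @param annotation data.frame with columns `gene_id`, `cds_length_bp`;
#'   may be omitted when `counts` is a `sim_dataset`.
#' @param patient_of_cell optional named vector mapping cell id to patient.
#' @return An `expression_matrix` list: `tpm`, `log2_tpm1`, `gene_ids`,
#'   `cell_ids`, `patient_of_cell`.
#' @export
tpm_from_counts <- function(counts, annotation = NULL, patient_of_cell = NULL) {
  if (inherits(counts, "sim_dataset")) {
    if (is.null(annotation))
      annotation <- data.frame(gene_id = counts$gene_ids,
                               cds_length_bp = unname(counts$cds_lengths))
    patient_of_cell <- patient_of_cell %||% counts$patient
    counts <- counts$counts
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("count matrix needs gene and cell dimnames")
  if (any(counts < 0)) stopf("count matrix has negative entries")
  lens <- setNames(annotation$cds_length_bp, annotation$gene_id)
  missing <- setdiff(rownames(counts), names(lens))
  if (length(missing) > 0)
    stopf("gene(s) missing from annotation: %s", paste(head(missing, 5), collapse = ", "))
  lens <- lens[rownames(counts)]
  if (any(is.na(lens)) || any(lens <= 0)) stopf("CDS lengths must be positive")

  rate <- counts / (lens / 1000)
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warnf("%d all-zero cell column(s) retained as zeros: %s", sum(zero),
          paste(head(colnames(counts)[zero], 5), collapse = ", "))
    tot[zero] <- 1
  }
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  structure(list(tpm = tpm,
                 log2_tpm1 = log_transform(tpm),
                 gene_ids = rownames(counts),
                 cell_ids = colnames(counts),
                 patient_of_cell = patient_of_cell),
            class = "expression_matrix")
}

#' Elementwise log2(x + 1)
#'
#' @param x non-negative matrix or vector (TPM values).
#' @return log2(x + 1), preserving dimensions and dimnames.
#' @export
log_transform <- function(x) {
  if (any(x < 0)) stopf("log_transform requires non-negative input")
  log2(x + 1)
}

#' Restrict an expression matrix to a cell subset
#' @param expr an `expression_matrix`.
#' @param cell_ids cells to keep.
#' @return The subset `expression_matrix`.
#' @export
subset_cells <- function(expr, cell_ids) {
  missing <- setdiff(cell_ids, expr$cell_ids)
  if (length(missing) > 0)
    stopf("unknown cell id(s): %s", paste(head(missing, 5), collapse = ", "))
  structure(list(tpm = expr$tpm[, cell_ids, drop = FALSE],
                 log2_tpm1 = expr$log2_tpm1[, cell_ids, drop = FALSE],
                 gene_ids = expr$gene_ids,
                 cell_ids = cell_ids,
                 patient_of_cell = expr$patient_of_cell[cell_ids]),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d cells (TPM and log2(TPM+1))\n",
              length(x$gene_ids), length(x$cell_ids)))
  invisible(x)
}
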