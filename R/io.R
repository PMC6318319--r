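# Readers and writers for the plain-text formats the pipeline consumes:
# dense TSV or MatrixMarket count matrices, gene annotation tables, per-cell
# QC metric tables, housekeeping gene lists, GMT gene-set collections, and
# survival cohort tables.

#' Read a gene x cell count matrix
#'
#' Accepts either a dense tab-separated file (first column = gene ids,
#' remaining columns = cells) or a MatrixMarket `.mtx` file with row/column
#' name sidecars (one id per line).
#'
#' @param path path to the TSV or MTX file.
#' @param genes_path,cells_path sidecar files with row (gene) and column
#'   (cell) ids; required when `path` is an MTX file.
#' @return An integer matrix with gene ids as rownames and cell ids as
#'   colnames.
#' @export
read_count_matrix <- function(path, genes_path = NULL, cells_path = NULL) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    if (is.null(genes_path) || is.null(cells_path))
      stopf("MTX input needs genes_path and cells_path sidecars")
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(genes_path)
    colnames(m) <- readLines(cells_path)
  } else {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
  }
  if (any(m < 0)) stopf("count matrix has negative entries")
  if (anyDuplicated(rownames(m))) stopf("duplicated gene ids in count matrix")
  if (anyDuplicated(colnames(m))) stopf("duplicated cell ids in count matrix")
  storage.mode(m) <- "double"
  m
}

#' Write a count (or expression) matrix
#'
#' @param m numeric matrix with dimnames.
#' @param path output path; a `.mtx` suffix selects MatrixMarket output with
#'   `<path>.genes.txt` / `<path>.cells.txt` sidecars, anything else a dense
#'   TSV with a leading `gene_id` column.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
    writeLines(rownames(m), paste0(path, ".genes.txt"))
    writeLines(colnames(m), paste0(path, ".cells.txt"))
  } else {
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a gene annotation table with CDS lengths
#'
#' @param path TSV with columns `gene_id` and `cds_length_bp`.
#' @return A data.frame with those two columns.
#' @export
read_gene_annotation <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "cds_length_bp") %in% names(df)))
    stopf("annotation must have columns gene_id and cds_length_bp")
  df
}

#' Read a per-cell QC metrics table
#'
#' @param path CSV or TSV file (delimiter inferred from the extension).
#' @param columns named character vector mapping the required fields
#'   (`cell_id`, `patient_id`, `total_reads`, `pct_mapped`, `median_tin`)
#'   to the header names used in the file, for tables with non-default
#'   headers.
#' @return A data.frame with the five canonical columns.
#' @export
read_qc_table <- function(path, columns = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("cell_id", "patient_id", "total_reads", "pct_mapped", "median_tin")
  if (!is.null(columns)) {
    for (canon in names(columns)) names(df)[names(df) == columns[[canon]]] <- canon
  }
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stopf("QC table lacks column(s): %s", paste(missing, collapse = ", "))
  df[need]
}

#' Read a housekeeping-gene list (one symbol per line)
#' @param path text file path.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Read a GMT gene-set collection
#'
#' Tab-separated lines: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (members), with the descriptions
#'   kept in the `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stopf("GMT line(s) with fewer than 3 fields: %s",
                      paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1)
  attr(sets, "description") <- vapply(parts, `[[`, "", 2)
  sets
}

#' Read a survival table
#'
#' @param path CSV with columns `sample_id`, `time_days`, `event`, and
#'   optionally `arm`.
#' @return A data.frame.
#' @export
read_survival_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time_days", "event")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stopf("survival table lacks column(s): %s", paste(missing, collapse = ", "))
  if (any(df$time_days < 0)) stopf("negative survival times")
  if (!all(df$event %in% c(0, 1))) stopf("event must be 0/1")
  df
}

#' Read a probe-to-gene map
#' @param path TSV with columns `probe_id` and `gene_id`.
#' @return A data.frame.
#' @export
read_probe_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_id") %in% names(df)))
    stopf("probe map must have columns probe_id and gene_id")
  if (anyDuplicated(df$probe_id)) stopf("a probe maps to more than one gene")
  df
}
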