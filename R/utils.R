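# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(x, y) if (is.null(x)) y else x

# row-wise standard deviations; type = "sample" uses the n-1 denominator
row_sds <- function(x, type = c("sample", "population")) {
  type <- match.arg(type)
  n <- ncol(x)
  v <- rowMeans(x^2) - rowMeans(x)^2
  v <- pmax(v, 0)
  if (type == "sample") {
    if (n < 2) return(rep(NA_real_, nrow(x)))
    v <- v * n / (n - 1)
  }
  sqrt(v)
}

col_sds <- function(x, type = "sample") row_sds(t(x), type)

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' used to compare recovered cluster labels with planted group truth.
#'
#' @param x,y vectors of labels of equal length.
#' @return A number in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(x, y) {
  if (length(x) != length(y)) stopf("labelings differ in length")
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  e <- b * cc / choose(n, 2)
  m <- (b + cc) / 2
  if (isTRUE(all.equal(m, e))) return(1)
  (a - e) / (m - e)
}

# Coerce a group specification (group_assignment object, factor, or named
# character vector) to a factor aligned with the given cell ids.
as_group_factor <- function(groups, cell_ids = NULL) {
  if (inherits(groups, "group_assignment")) groups <- groups$label_of_cell
  if (!is.null(names(groups)) && !is.null(cell_ids)) {
    missing <- setdiff(cell_ids, names(groups))
    if (length(missing) > 0)
      stopf("no group label for cell(s): %s", paste(head(missing, 5), collapse = ", "))
    groups <- groups[cell_ids]
  }
  factor(as.character(groups))
}

# Extract the log2(TPM+1) matrix from an expression_matrix or pass a plain
# matrix through unchanged.
as_log_matrix <- function(expr) {
  if (inherits(expr, "expression_matrix")) return(expr$log2_tpm1)
  if (is.matrix(expr)) return(expr)
  stopf("expected an expression_matrix or a numeric matrix")
}
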