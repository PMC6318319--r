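# Per-gene summary statistics and the two gene filters: the coefficient-of-
# variation selection of highly variable genes (CV >= 0.5 with mean
# log2(TPM+1) >= 3, both inclusive) and the Seurat-style prefilter
# (expressed in more than two cells, log2 mean > 1, sd > 1, all strict).
#
# CV is computed on the linear TPM scale by default (sd/mean of TPM);
# `cv_scale = "log"` switches to sd/mean of log2(TPM+1). See the methods
# vignette for why linear is the default.

#' Per-gene expression statistics
#'
#' @param expr an `expression_matrix` (from [tpm_from_counts()]).
#' @param hk_list character vector of housekeeping gene ids (for flagging
#'   and depletion accounting); may be empty.
#' @param cv_scale `"linear"` (sd/mean of TPM, the default) or `"log"`
#'   (sd/mean of log2(TPM+1)).
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return data.frame with one row per gene: `gene_id`, `mean_log`,
#'   `sd_log`, `cv`, `n_cells_expressed`, `is_housekeeping`. Genes with
#'   zero mean have `cv = 0` by convention.
#' @export
compute_gene_stats <- function(expr, hk_list = character(),
                               cv_scale = c("linear", "log"),
                               sd_type = c("sample", "population")) {
  cv_scale <- match.arg(cv_scale)
  sd_type <- match.arg(sd_type)
  if (!inherits(expr, "expression_matrix")) stopf("expr must be an expression_matrix")
  if (length(expr$cell_ids) == 0 || length(expr$gene_ids) == 0)
    stopf("empty expression matrix")
  lg <- expr$log2_tpm1
  mean_log <- rowMeans(lg)
  sd_log <- row_sds(lg, sd_type)
  if (cv_scale == "linear") {
    m <- rowMeans(expr$tpm)
    s <- row_sds(expr$tpm, sd_type)
    cv <- ifelse(m > 0, s / m, 0)
  } else {
    cv <- ifelse(mean_log > 0, sd_log / mean_log, 0)
  }
  data.frame(gene_id = expr$gene_ids,
             mean_log = mean_log,
             sd_log = sd_log,
             cv = cv,
             n_cells_expressed = rowSums(expr$tpm > 0),
             is_housekeeping = expr$gene_ids %in% hk_list,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Coefficient-of-variation selection of variable genes
#'
#' Selects genes with `cv >= cv_min` and `mean_log >= mean_log_min` (both
#' inclusive), and reports what fraction of the selected set -- and of the
#' complementary "stable" set (mean above threshold, CV below) -- is
#' housekeeping, mirroring the housekeeping-depletion accounting used to
#' justify the CV approach.
#'
#' @param stats output of [compute_gene_stats()].
#' @param cv_min CV cutoff (default 0.5).
#' @param mean_log_min mean log2(TPM+1) cutoff (default 3).
#' @return A `gene_selection` list: `selected_ids`, `criteria`,
#'   `hk_fraction_selected`, `hk_fraction_stable`, `n_selected`.
#' @export
select_variable_genes <- function(stats, cv_min = 0.5, mean_log_min = 3) {
  sel <- stats$cv >= cv_min & stats$mean_log >= mean_log_min
  stable <- stats$cv <= cv_min & stats$mean_log >= mean_log_min
  frac <- function(idx) if (any(idx)) mean(stats$is_housekeeping[idx]) else 0
  structure(list(selected_ids = stats$gene_id[sel],
                 criteria = c(cv_min = cv_min, mean_log_min = mean_log_min),
                 hk_fraction_selected = frac(sel),
                 hk_fraction_stable = frac(stable),
                 n_selected = sum(sel)),
            class = "gene_selection")
}

#' Seurat-style gene prefilter
#'
#' Keeps genes expressed in more than `min_cells` cells with mean
#' log2(TPM+1) strictly above `min_mean_log` and sd strictly above
#' `min_sd`. This is the prefilter used ahead of embedding/visualization;
#' it is independent of the CV selection.
#'
#' @param expr an `expression_matrix`, or a precomputed stats data.frame
#'   from [compute_gene_stats()].
#' @param min_cells cell-count bound (strict >; default 2).
#' @param min_mean_log mean bound (strict >; default 1).
#' @param min_sd sd bound (strict >; default 1).
#' @return Character vector of kept gene ids.
#' @export
seurat_prefilter <- function(expr, min_cells = 2, min_mean_log = 1, min_sd = 1) {
  stats <- if (is.data.frame(expr)) expr else compute_gene_stats(expr)
  keep <- stats$n_cells_expressed > min_cells &
    stats$mean_log > min_mean_log &
    stats$sd_log > min_sd
  stats$gene_id[keep]
}

#' @export
print.gene_selection <- function(x, ...) {
  cat(sprintf("gene_selection: %d genes (cv >= %g, mean_log >= %g)\n",
              x$n_selected, x$criteria["cv_min"], x$criteria["mean_log_min"]))
  cat(sprintf("  housekeeping: %.1f%% of selected vs %.1f%% of stable genes\n",
              100 * x$hk_fraction_selected, 100 * x$hk_fraction_stable))
  invisible(x)
}
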