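# End-to-end orchestration: qc -> normalize -> select -> cluster ->
# signature (-> survive when a cohort is supplied), with parameters, seed
# and output checksums logged so a rerun with the same config reproduces
# identical outputs. Also ships the per-patient cell-distribution fixture
# and its summary arithmetic.

#' Load the packaged per-patient cell-distribution fixture
#'
#' Per-patient rows: cells sequenced, cells passing QC, and the L1-L4 group
#' counts, with cytogenetics. The flattened source table left a few group
#' placements ambiguous; each resolved placement is annotated in the `note`
#' column.
#'
#' @return data.frame with columns `sample_id`, `stage`, `n_sequenced`,
#'   `n_passed`, `L1`..`L4`, `cytogenetics`, `note`.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_cell_distribution.csv",
                      package = "scmmsig", mustWork = TRUE)
  read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Summarize a per-patient cell-distribution table
#'
#' Column sums plus percentages rounded to the nearest integer (pass rate
#' relative to cells sequenced; group percentages relative to cells
#' analyzed).
#'
#' @param fixture data.frame in the layout of [load_table1_fixture()].
#' @return A list: `n_sequenced`, `n_passed`, `pct_passed`, `group_totals`,
#'   `group_pct`.
#' @export
summarize_table1 <- function(fixture = load_table1_fixture()) {
  group_cols <- grep("^L[0-9]+$", names(fixture), value = TRUE)
  if (nrow(fixture) == 0) {
    return(list(n_sequenced = 0, n_passed = 0, pct_passed = NA_real_,
                group_totals = setNames(numeric(length(group_cols)), group_cols),
                group_pct = setNames(rep(NA_real_, length(group_cols)), group_cols)))
  }
  gsum <- rowSums(fixture[group_cols])
  bad <- which(gsum != fixture$n_passed | fixture$n_passed > fixture$n_sequenced)
  if (length(bad) > 0)
    stopf("inconsistent fixture row: %s", fixture$sample_id[bad[1]])
  n_seq <- sum(fixture$n_sequenced)
  n_pass <- sum(fixture$n_passed)
  gt <- colSums(fixture[group_cols])
  list(n_sequenced = n_seq,
       n_passed = n_pass,
       pct_passed = round(100 * n_pass / n_seq),
       group_totals = gt,
       group_pct = round(100 * gt / n_pass))
}

#' Run the full analysis pipeline
#'
#' Executes QC filtering, TPM normalization, variable-gene selection,
#' clustering into ordered groups, signature derivation and (when survival
#' inputs are present) cohort stratification, writing each stage's outputs
#' under `config$outdir` and returning a run report with parameters and
#' md5 checksums of every written file.
#'
#' @param config a list (or path to a JSON/YAML file encoding one) with
#'   elements:
#'   \describe{
#'     \item{counts, annotation, qc_metrics}{paths to the count matrix,
#'       gene annotation and QC table (or in-memory equivalents); a
#'       `sim_dataset` may be passed as `dataset` instead of
#'       counts/annotation.}
#'     \item{housekeeping}{optional path to (or vector of) housekeeping
#'       gene symbols.}
#'     \item{gmt}{optional path to (or named list of) gene sets.}
#'     \item{survival}{optional list with `expression` (sample x probe
#'       matrix or path), `probe_map` (optional), `survival_table`,
#'       and optional `signature_genes` overriding the derived signature.}
#'     \item{thresholds}{optional overrides: `min_total_reads`,
#'       `min_pct_mapped`, `min_median_tin`, `cv_min`, `mean_log_min`,
#'       `fc_min`, `p_max`, `k`, `kmeans_restarts`.}
#'     \item{outdir}{output directory (required).}
#'     \item{seed}{seed for the stochastic stages (K-means restarts).}
#'   }
#' @return A `pipeline_report` list with per-stage summaries, the
#'   parameters used, and `checksums` (md5 of every output file).
#' @export
run_all <- function(config) {
  if (is.character(config) && length(config) == 1) config <- read_pipeline_config(config)
  if (is.null(config$outdir)) stopf("config$outdir is required")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds %||% list()
  seed <- config$seed %||% 1
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(config$outdir, name)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
    p
  }
  stage <- "qc"
  report <- tryCatch({
    # --- qc ---------------------------------------------------------------
    qc_tab <- config$qc_metrics
    if (is.character(qc_tab)) qc_tab <- read_qc_table(qc_tab)
    thresholds <- qc_thresholds(th$min_total_reads %||% 1e6,
                                th$min_pct_mapped %||% 55,
                                th$min_median_tin %||% 45)
    qc <- filter_cells(qc_tab, thresholds)
    emit(data.frame(cell_id = qc$pass_ids), "qc_pass_cells.csv")
    emit(data.frame(cell_id = names(qc$fail_records),
                    reasons = vapply(qc$fail_records, paste, "", collapse = ";")),
         "qc_fail_reasons.csv")

    # --- normalize --------------------------------------------------------
    stage <- "normalize"
    if (!is.null(config$dataset)) {
      expr <- tpm_from_counts(config$dataset)
    } else {
      counts <- config$counts
      if (is.character(counts)) counts <- read_count_matrix(counts)
      ann <- config$annotation
      if (is.character(ann)) ann <- read_gene_annotation(ann)
      expr <- tpm_from_counts(counts, ann)
    }
    keep <- intersect(expr$cell_ids, qc$pass_ids)
    if (length(keep) < 2) stopf("fewer than 2 cells pass QC")
    expr <- subset_cells(expr, keep)

    # --- select -----------------------------------------------------------
    stage <- "select"
    hk <- config$housekeeping %||% character(0)
    if (is.character(hk) && length(hk) == 1 && file.exists(hk)) hk <- read_gene_list(hk)
    stats <- compute_gene_stats(expr, hk_list = hk)
    sel <- select_variable_genes(stats, th$cv_min %||% 0.5, th$mean_log_min %||% 3)
    if (sel$n_selected < 2) stopf("fewer than 2 variable genes selected")
    emit(stats, "gene_stats.csv")
    emit(data.frame(gene_id = sel$selected_ids), "selected_genes.csv")

    # --- cluster ----------------------------------------------------------
    stage <- "cluster"
    k <- th$k %||% 4
    ga <- cluster_cells(expr, genes = sel$selected_ids, k = k)
    emit(data.frame(cell_id = names(ga$label_of_cell),
                    patient_id = (expr$patient_of_cell %||%
                                  setNames(rep(NA, length(keep)), keep))[names(ga$label_of_cell)],
                    label = unname(ga$label_of_cell)),
         "cell_groups.csv")
    emit(data.frame(step = seq_along(ga$dendrogram$height),
                    left = ga$dendrogram$merge[, 1],
                    right = ga$dendrogram$merge[, 2],
                    height = ga$dendrogram$height),
         "dendrogram_merges.csv")

    # --- signature --------------------------------------------------------
    stage <- "signature"
    de <- anova_per_gene(expr, ga)
    sig <- adjacent_monotone_signature(expr, ga,
                                       fc_min = th$fc_min %||% 2,
                                       p_max = th$p_max %||% 0.05)
    emit(de, "anova_per_gene.csv")
    emit(data.frame(gene_id = sig$common_up), "common_upregulated.csv")
    emit(data.frame(gene_id = sig$adjacent_monotone), "signature_genes.csv")
    overlap <- NULL
    if (!is.null(config$gmt)) {
      sets <- config$gmt
      if (is.character(sets)) sets <- read_gmt(sets)
      overlap <- geneset_overlap(sig$adjacent_monotone, sets,
                                 universe_size = length(expr$gene_ids))
      emit(overlap, "geneset_overlap.csv")
    }

    # --- survive (optional) ----------------------------------------------
    stage <- "survive"
    strat <- NULL
    if (!is.null(config$survival)) {
      sv <- config$survival
      intens <- sv$expression
      if (is.character(intens)) {
        intens <- as.matrix(read.csv(intens, row.names = 1, check.names = FALSE))
      }
      recs <- sv$survival_table
      if (is.character(recs)) recs <- read_survival_table(recs)
      pmap <- sv$probe_map
      if (is.character(pmap)) pmap <- read_probe_map(pmap)
      sig_genes <- sv$signature_genes %||% sig$adjacent_monotone
      strat <- stratify_survival(intens, recs, sig_genes, probe_map = pmap,
                                 n_restarts = th$kmeans_restarts %||% 25,
                                 seed = seed)
      emit(data.frame(sample_id = names(strat$risk_groups$label_of_sample),
                      label = unname(strat$risk_groups$label_of_sample)),
           "risk_groups.csv")
      emit(data.frame(chi_square = strat$logrank$chi_square, p = strat$logrank$p,
                      hr = strat$cox$hr, ci_low = strat$cox$ci_low,
                      ci_high = strat$cox$ci_high,
                      hr_mantel_haenszel = strat$cox$hr_mantel_haenszel),
           "survival_tests.csv")
    }

    list(qc = qc$summary,
         n_cells_analyzed = length(keep),
         n_genes_selected = sel$n_selected,
         group_sizes = table(ga$label_of_cell),
         n_common_up = length(sig$common_up),
         n_signature = length(sig$adjacent_monotone),
         overlap_top = if (!is.null(overlap)) head(overlap, 5) else NULL,
         survival = if (!is.null(strat)) {
           list(n = strat$n_samples, logrank_p = strat$logrank$p,
                hr = strat$cox$hr)
         } else "skipped")
  }, error = function(e) {
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })

  report$parameters <- list(thresholds = th, seed = seed, k = th$k %||% 4)
  report$checksums <- md5sum(sort(paths))
  class(report) <- "pipeline_report"
  report
}

read_pipeline_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("YAML config requires the yaml package; use JSON instead")
    yaml::yaml.load_file(path)
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stopf("JSON config requires the jsonlite package")
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline run: %d cells analyzed, %d genes selected\n",
              x$n_cells_analyzed, x$n_genes_selected))
  cat(sprintf("  signature: %d common up-regulated, %d adjacent-monotone\n",
              x$n_common_up, x$n_signature))
  if (!identical(x$survival, "skipped"))
    cat(sprintf("  survival: n = %d, log-rank p = %.3g, HR = %.3f\n",
                x$survival$n, x$survival$logrank_p, x$survival$hr))
  else cat("  survival: skipped (no cohort supplied)\n")
  invisible(x)
}
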