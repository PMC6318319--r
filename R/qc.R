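# Cell-level quality control: three sequencing-quality criteria, each a
# strict lower bound -- a cell is low quality iff its reads, mapping rate or
# median transcript integrity number fall strictly below threshold.

#' QC thresholds for cell filtering
#'
#' A cell fails when total reads < `min_total_reads`, percent mapped <
#' `min_pct_mapped`, or median non-zero transcript integrity number (TIN) <
#' `min_median_tin`. Values exactly at a threshold pass (the criteria are
#' phrased as strict "below" rules).
#'
#' @param min_total_reads minimum reads per cell (default 1e6).
#' @param min_pct_mapped minimum percentage of mapped reads (default 55).
#' @param min_median_tin minimum median TIN over non-zero transcripts
#'   (default 45).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_total_reads = 1e6, min_pct_mapped = 55,
                          min_median_tin = 45) {
  if (any(c(min_total_reads, min_pct_mapped, min_median_tin) < 0))
    stopf("thresholds must be non-negative")
  structure(list(min_total_reads = min_total_reads,
                 min_pct_mapped = min_pct_mapped,
                 min_median_tin = min_median_tin),
            class = "qc_thresholds")
}

#' Filter cells by sequencing-quality criteria
#'
#' @param records data.frame of per-cell QC records with columns `cell_id`,
#'   `total_reads`, `pct_mapped`, `median_tin` (and optionally
#'   `patient_id`).
#' @param thresholds a [qc_thresholds()].
#' @return A `qc_result` list: `pass_ids` (cells passing all criteria),
#'   `fail_records` (named list mapping failing cell id to its violated
#'   criteria), and `summary` (per-criterion failure counts).
#' @export
filter_cells <- function(records, thresholds = qc_thresholds()) {
  if (!inherits(thresholds, "qc_thresholds")) stopf("thresholds must be qc_thresholds")
  need <- c("cell_id", "total_reads", "pct_mapped", "median_tin")
  missing <- setdiff(need, names(records))
  if (length(missing) > 0)
    stopf("QC records lack column(s): %s", paste(missing, collapse = ", "))
  if (anyDuplicated(records$cell_id)) stopf("duplicated cell ids in QC table")
  for (col in c("total_reads", "pct_mapped", "median_tin")) {
    bad <- which(is.na(records[[col]]))
    if (length(bad) > 0)
      stopf("missing %s for cell %s", col, records$cell_id[bad[1]])
  }
  if (any(records$pct_mapped < 0 | records$pct_mapped > 100))
    stopf("pct_mapped outside [0, 100]")
  if (any(records$total_reads < 0)) stopf("negative total_reads")

  viol <- cbind(total_reads = records$total_reads < thresholds$min_total_reads,
                pct_mapped = records$pct_mapped < thresholds$min_pct_mapped,
                median_tin = records$median_tin < thresholds$min_median_tin)
  fails <- rowSums(viol) > 0
  fail_records <- lapply(which(fails), function(i) colnames(viol)[viol[i, ]])
  names(fail_records) <- records$cell_id[fails]
  structure(list(pass_ids = records$cell_id[!fails],
                 fail_records = fail_records,
                 summary = c(n_input = nrow(records),
                             n_pass = sum(!fails),
                             n_fail = sum(fails),
                             colSums(viol)),
                 thresholds = thresholds),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("QC result: %d/%d cells pass (%d fail)\n",
              x$summary["n_pass"], x$summary["n_input"], x$summary["n_fail"]))
  cat(sprintf("  failures by criterion: reads %d, mapped %d, tin %d\n",
              x$summary["total_reads"], x$summary["pct_mapped"],
              x$summary["median_tin"]))
  invisible(x)
}
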