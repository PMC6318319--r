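# scmmsig

Single-cell expression signatures of multiple myeloma progression.

Plasma cells in multiple myeloma are molecularly heterogeneous even within
one patient: single cells from a single biopsy can sit at different points
along the progression axis from premalignant (MGUS) to relapsed/refractory
disease. `scmmsig` is an R package for the analysis that makes this
visible in single-cell RNA-seq of CD138-selected plasma cells and turns it
into a prognostic gene signature. It is aimed at computational biologists
working with plate/microfluidics-style (full-length, deeply sequenced)
single-cell data plus an external expression cohort with outcomes.

The pipeline:

1. **QC** — keep cells with total reads ≥ 10⁶, ≥ 55% mapped, median
   non-zero transcript integrity number (TIN) ≥ 45 (strict "below fails";
   boundary values pass).
2. **Normalization** — CDS-restricted counts to TPM,
   `tpm_g = 10⁶ (c_g/L_g) / Σ_g (c_g/L_g)`, analysed as log₂(TPM+1).
3. **Gene selection** — coefficient of variation CV ≥ 0.5 with mean
   log₂(TPM+1) ≥ 3 (housekeeping genes should be depleted); a
   Seurat-style prefilter (> 2 cells, log₂ mean > 1, sd > 1) is provided
   separately.
4. **Clustering** — 1 − Pearson correlation distance on the selected
   genes, Ward.D2 linkage (Lance–Williams on squared dissimilarities,
   square-root heights), cut at k = 4, groups relabeled L1..L4 in
   ascending mean expression.
5. **Signature** — per-gene one-way ANOVA (log₂ scale) and pairwise
   screening at FC ≥ 2 (i.e. Δ mean log₂ ≥ 1) and p < 0.05: the *common
   up-regulated* set passes versus L1 in every group, the
   *adjacent-monotone signature* additionally passes every adjacent step
   L1→L2→L3→L4; hypergeometric over-representation against GMT
   collections.
6. **Survival** — an external sample × probe cohort is collapsed to genes
   (mean over probes), standardized, restricted to the signature,
   dichotomized high/low by Hartigan–Wong K-means, and compared by
   Kaplan–Meier curves, the Mantel–Cox log-rank test, and Cox (Efron
   ties) plus Mantel–Haenszel hazard ratios.

A negative-binomial simulator (`simulate_expression()`,
`simulate_qc_metrics()`, `simulate_survival_cohort()`) plants known group
structure, housekeeping stability, and signature-linked hazard so every
stage is testable without external data. See `vignettes/methods.Rmd` for
the model, parameter rationale, and what the synthetic world does and does
not establish.

## Worked example

A balanced synthetic cohort (4 patients, 40 cells each, one latent group
per patient, planted 200-gene program stepping 1.5 log₂ per group):

```r
library(scmmsig)

cfg <- sim_config(n_patients = 4, cells_per_patient = c(40, 40),
                  group_mixture = diag(4), seed = 1)
ds <- simulate_expression(cfg)

qc_tab <- simulate_qc_metrics(length(ds$cell_ids), n_fail_reads = 6,
                              n_fail_mapped = 3, n_fail_tin = 3, seed = 1)
qc_tab$cell_id <- ds$cell_ids
qc <- filter_cells(qc_tab)
#> QC result: 148/160 cells pass (12 fail)
#>   failures by criterion: reads 6, mapped 3, tin 3

expr <- subset_cells(tpm_from_counts(ds), qc$pass_ids)
sel <- select_variable_genes(compute_gene_stats(expr, ds$true_housekeeping_genes))
#> gene_selection: 403 genes (cv >= 0.5, mean_log >= 3)
#>   housekeeping: 0.0% of selected vs 11.9% of stable genes

ga <- cluster_cells(expr, sel$selected_ids, k = 4)
#> group_assignment: 148 cells in 4 ordered groups
#> L1 L2 L3 L4
#> 28 40 40 40
adjusted_rand_index(ga$label_of_cell, ds$true_group[names(ga$label_of_cell)])
#> 1

sig <- adjacent_monotone_signature(expr, ga)
#> signature_result: 198 common up-regulated, 198 adjacent-monotone (FC >= 2, p < 0.05)
sum(ds$true_progression_genes %in% sig$adjacent_monotone)
#> 198   # of 200 planted genes

sv <- simulate_survival_cohort(survival_sim_config(true_hr = 1.83, seed = 1))
colnames(sv$expression) <- sig$adjacent_monotone[seq_len(ncol(sv$expression))]
stratify_survival(sv$expression, sv$survival, colnames(sv$expression), seed = 1)
#> survival stratification: n = 300
#> log-rank: chi-square = 12.290, p = 0.000455
#> Cox HR = 1.586 (95% CI 1.223-2.056); Mantel-Haenszel HR = 1.546
```

Reading the output: the QC stage drops exactly the planted low-quality
cells; CV selection keeps the planted program while excluding every
housekeeping gene (0% vs 11.9% among stable genes); clustering recovers
the four planted groups perfectly (adjusted Rand index 1) and labels them
in ascending expression; the monotone signature recovers 198/200 planted
genes with no false positives; and the cohort dichotomized on that
signature shows significantly worse survival in the high group (HR 1.59
against a planted hazard ratio of 1.83 for the upper score half — a single
cohort draw, attenuated by the sharp-threshold planted effect).

The packaged per-patient fixture reproduces the source study's cell
accounting exactly:

```r
summarize_table1()
#> 701 sequenced, 597 analyzed (85%), groups L1-L4 = 89/237/158/113 (15/40/26/19%)
```

## Command line

`inst/cli/scmmsig` exposes the stages as subcommands (`simulate`, `qc`,
`normalize`, `select`, `cluster`, `signature`, `survive`, `run-all`,
`table1`), e.g.

```sh
Rscript inst/cli/scmmsig simulate --out sim/ --seed 1
Rscript inst/cli/scmmsig qc --metrics sim/qc.csv --min-reads 1000000 --out out/
```

`run_all()` (or `run-all --config cfg.json`) chains every stage, logs
parameters and seeds, and writes md5 checksums of all outputs; identical
configs reproduce identical checksums.

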