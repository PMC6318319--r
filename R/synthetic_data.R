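# Synthetic single-cell expression, QC-metric, and survival-cohort
# generators. These emulate the statistical structure the downstream
# analysis assumes -- a few hundred plasma cells from ~15 patients, four
# latent groups with a progressively up-regulated gene program, stable
# housekeeping genes, and an independent cohort whose hazard is linked to
# the planted signature -- so that every stage can be tested against known
# truth.

#' Configuration for the single-cell expression simulator
#'
#' Counts are drawn from a negative-binomial model on a per-gene mean with
#' log-normal cell size factors. Housekeeping genes share a high baseline
#' and low dispersion; progression genes get a log2 mean offset of
#' `delta_log2 * (group - 1)` in latent groups 1..`n_groups`.
#'
#' @param n_patients number of patients.
#' @param cells_per_patient integer range (min, max); each patient's cell
#'   count is drawn uniformly from it.
#' @param n_genes total genes.
#' @param n_housekeeping planted stable housekeeping genes.
#' @param n_progression_genes planted progression-program genes.
#' @param n_groups latent group count (the four risk groups by default).
#' @param delta_log2 per-adjacent-group expression step of the planted
#'   program, in log2 units.
#' @param baseline_log2_mean_range interval for background-gene baseline
#'   log2 relative abundance.
#' @param housekeeping_log2_range interval for housekeeping baselines
#'   (higher and narrower than background).
#' @param progression_tpm_l1_range interval for the planted genes' TPM in
#'   the lowest group; chosen so the program is moderately expressed.
#' @param dispersion negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2) for non-housekeeping genes.
#' @param dispersion_housekeeping overdispersion for housekeeping genes.
#' @param library_size expected total counts per cell.
#' @param size_factor_sdlog sdlog of the log-normal per-cell size factors.
#' @param group_mixture optional `n_patients x n_groups` matrix of per-
#'   patient group probabilities (rows sum to 1). The default gives each
#'   patient one dominant group plus minor fractions of the others.
#' @param seed random seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_patients = 15,
                       cells_per_patient = c(7, 77),
                       n_genes = 2500,
                       n_housekeeping = 250,
                       n_progression_genes = 200,
                       n_groups = 4,
                       delta_log2 = 1.5,
                       baseline_log2_mean_range = c(0, 6),
                       housekeeping_log2_range = c(5, 7),
                       progression_tpm_l1_range = c(8, 16),
                       dispersion = 0.2,
                       dispersion_housekeeping = 0.05,
                       library_size = 2e6,
                       size_factor_sdlog = 0.25,
                       group_mixture = NULL,
                       seed = 1) {
  cfg <- list(n_patients = n_patients, cells_per_patient = cells_per_patient,
              n_genes = n_genes, n_housekeeping = n_housekeeping,
              n_progression_genes = n_progression_genes, n_groups = n_groups,
              delta_log2 = delta_log2,
              baseline_log2_mean_range = baseline_log2_mean_range,
              housekeeping_log2_range = housekeeping_log2_range,
              progression_tpm_l1_range = progression_tpm_l1_range,
              dispersion = dispersion,
              dispersion_housekeeping = dispersion_housekeeping,
              library_size = library_size,
              size_factor_sdlog = size_factor_sdlog,
              group_mixture = group_mixture, seed = seed)
  with(cfg, {
    if (any(c(n_patients, n_genes, n_groups) < 1)) stopf("counts must be positive")
    if (n_housekeeping < 0 || n_progression_genes < 0) stopf("counts must be positive")
    if (n_housekeeping + n_progression_genes > n_genes)
      stopf("n_housekeeping + n_progression_genes exceeds n_genes")
    if (delta_log2 < 0) stopf("delta_log2 must be >= 0")
    if (dispersion <= 0 || dispersion_housekeeping <= 0) stopf("dispersion must be > 0")
    if (length(cells_per_patient) != 2 || cells_per_patient[1] < 1 ||
        cells_per_patient[1] > cells_per_patient[2])
      stopf("cells_per_patient must be an increasing positive range")
  })
  if (is.null(cfg$group_mixture)) {
    cfg$group_mixture <- default_group_mixture(n_patients, n_groups)
  } else {
    gm <- as.matrix(cfg$group_mixture)
    if (nrow(gm) != n_patients || ncol(gm) != n_groups)
      stopf("group_mixture must be n_patients x n_groups")
    if (any(gm < 0) || any(abs(rowSums(gm) - 1) > 1e-8))
      stopf("group_mixture rows must be probability vectors summing to 1")
    cfg$group_mixture <- gm
  }
  structure(cfg, class = "sim_config")
}

# One dominant group per patient (cycling through groups) with minor
# fractions of the others decaying with group distance, so each patient
# spans at least two groups.
default_group_mixture <- function(n_patients, n_groups) {
  t(vapply(seq_len(n_patients), function(p) {
    dom <- ((p - 1) %% n_groups) + 1
    w <- 2^(-abs(seq_len(n_groups) - dom))
    w[dom] <- 0
    if (sum(w) > 0) w <- 0.25 * w / sum(w)
    w[dom] <- 1 - sum(w)
    w
  }, numeric(n_groups)))
}

#' Simulate a single-cell count dataset with planted group structure
#'
#' @param config a [sim_config()].
#' @return A `sim_dataset` list with elements `counts` (gene x cell integer
#'   matrix), `cds_lengths` (named, bp), `true_group` (per-cell index in
#'   1..n_groups), `patient` (per-cell id), `true_progression_genes`,
#'   `true_housekeeping_genes`, `gene_ids`, `cell_ids`, and the `config`.
#' @export
simulate_expression <- function(config) {
  if (!inherits(config, "sim_config")) stopf("config must be a sim_config")
  set.seed(config$seed)
  G <- config$n_groups
  n_hk <- config$n_housekeeping
  n_pg <- config$n_progression_genes
  n_bg <- config$n_genes - n_hk - n_pg

  gene_ids <- c(sprintf("HK%04d", seq_len(n_hk)),
                sprintf("PG%04d", seq_len(n_pg)),
                sprintf("BG%04d", seq_len(n_bg)))
  is_pg <- seq_len(config$n_genes) %in% (n_hk + seq_len(n_pg))

  # cells
  cell_range <- seq(config$cells_per_patient[1], config$cells_per_patient[2])
  n_cells_p <- cell_range[sample.int(length(cell_range), config$n_patients,
                                     replace = TRUE)]
  patient <- rep(sprintf("P%02d", seq_len(config$n_patients)), n_cells_p)
  N <- length(patient)
  grp <- unlist(lapply(seq_len(config$n_patients), function(p) {
    sample.int(G, n_cells_p[p], replace = TRUE, prob = config$group_mixture[p, ])
  }))
  cell_ids <- sprintf("%s_C%03d", patient, unlist(lapply(n_cells_p, seq_len)))

  # per-gene baselines (relative abundance units)
  w_hk <- 2^runif(n_hk, config$housekeeping_log2_range[1], config$housekeeping_log2_range[2])
  w_bg <- 2^runif(n_bg, config$baseline_log2_mean_range[1], config$baseline_log2_mean_range[2])
  t_pg <- runif(n_pg, config$progression_tpm_l1_range[1], config$progression_tpm_l1_range[2])
  # solve planted baselines so their group-1 TPM equals the drawn targets
  s_other <- sum(w_hk) + sum(w_bg)
  share <- sum(t_pg) / 1e6
  w_pg <- t_pg / sum(t_pg) * (s_other * share / (1 - share))
  w <- c(w_hk, w_pg, w_bg)

  phi <- c(rep(config$dispersion_housekeeping, n_hk), rep(config$dispersion, n_pg + n_bg))
  cds_lengths <- setNames(round(runif(config$n_genes, 300, 5000)), gene_ids)

  # group-level true TPM profiles and count sampling probabilities
  tpm_true <- vapply(seq_len(G), function(g) {
    wg <- w
    wg[is_pg] <- wg[is_pg] * 2^(config$delta_log2 * (g - 1))
    wg / sum(wg) * 1e6
  }, numeric(config$n_genes))
  weight <- tpm_true * cds_lengths
  pmat <- sweep(weight, 2, colSums(weight), "/")

  sf <- exp(rnorm(N, 0, config$size_factor_sdlog))
  mu <- pmat[, grp, drop = FALSE] * rep(config$library_size * sf, each = config$n_genes)
  counts <- matrix(rnbinom(length(mu), size = rep(1 / phi, N), mu = mu),
                   nrow = config$n_genes, ncol = N,
                   dimnames = list(gene_ids, cell_ids))

  structure(list(counts = counts,
                 cds_lengths = cds_lengths,
                 true_group = setNames(grp, cell_ids),
                 patient = setNames(patient, cell_ids),
                 true_progression_genes = gene_ids[is_pg],
                 true_housekeeping_genes = gene_ids[seq_len(n_hk)],
                 gene_ids = gene_ids, cell_ids = cell_ids,
                 config = config),
            class = "sim_dataset")
}

#' Simulate a per-cell QC metrics table with planted failures
#'
#' Exactly `n_fail_reads`, `n_fail_mapped` and `n_fail_tin` non-overlapping
#' cells violate, respectively, the read-count, mapping-rate and transcript-
#' integrity thresholds; every other cell strictly satisfies all three.
#'
#' @param n_cells total cells.
#' @param n_fail_reads,n_fail_mapped,n_fail_tin planted failure counts.
#' @param seed random seed.
#' @param thresholds a [qc_thresholds()] the planted values respect.
#' @return A data.frame of per-cell QC records with a `planted_fail` column
#'   recording the violated criterion ("" for passing cells).
#' @export
simulate_qc_metrics <- function(n_cells, n_fail_reads = 0, n_fail_mapped = 0,
                                n_fail_tin = 0, seed = 1,
                                thresholds = qc_thresholds()) {
  counts <- c(n_cells, n_fail_reads, n_fail_mapped, n_fail_tin)
  if (any(counts < 0)) stopf("cell and failure counts must be non-negative")
  if (n_fail_reads + n_fail_mapped + n_fail_tin > n_cells)
    stopf("planted failures exceed n_cells")
  set.seed(seed)
  df <- data.frame(
    cell_id = sprintf("cell%04d", seq_len(n_cells)),
    patient_id = if (n_cells > 0) sprintf("P%02d", ((seq_len(n_cells) - 1) %% 5) + 1) else character(0),
    total_reads = round(runif(n_cells, thresholds$min_total_reads * 1.2,
                              thresholds$min_total_reads * 6)),
    pct_mapped = runif(n_cells, thresholds$min_pct_mapped + 5, 95),
    median_tin = runif(n_cells, thresholds$min_median_tin + 5, 85),
    planted_fail = rep("", n_cells),
    stringsAsFactors = FALSE)
  idx <- seq_len(n_fail_reads + n_fail_mapped + n_fail_tin)
  if (n_fail_reads > 0) {
    i <- idx[seq_len(n_fail_reads)]
    df$total_reads[i] <- round(runif(n_fail_reads, thresholds$min_total_reads * 0.1,
                                     thresholds$min_total_reads * 0.99))
    df$planted_fail[i] <- "total_reads"
  }
  if (n_fail_mapped > 0) {
    i <- idx[n_fail_reads + seq_len(n_fail_mapped)]
    df$pct_mapped[i] <- runif(n_fail_mapped, 5, thresholds$min_pct_mapped * 0.98)
    df$planted_fail[i] <- "pct_mapped"
  }
  if (n_fail_tin > 0) {
    i <- idx[n_fail_reads + n_fail_mapped + seq_len(n_fail_tin)]
    df$median_tin[i] <- runif(n_fail_tin, 5, thresholds$min_median_tin * 0.98)
    df$planted_fail[i] <- "median_tin"
  }
  df
}

#' Configuration for the synthetic survival cohort
#'
#' Each sample gets a latent signature score; signature-gene expression is
#' score plus Gaussian noise. Event times are exponential, with the hazard
#' multiplied by `true_hr` for the upper half of scores; censoring is an
#' independent exponential clock.
#'
#' @param n_samples cohort size.
#' @param n_signature_genes number of signature genes measured.
#' @param true_hr planted hazard ratio (high vs low score half).
#' @param baseline_hazard events per day for the low half.
#' @param censor_rate independent censoring hazard per day (0 = none).
#' @param arms named numeric vector of treatment-arm proportions (sum 1).
#' @param noise_sd sd of per-gene measurement noise around the score.
#' @param seed random seed.
#' @return A validated `survival_sim_config` list.
#' @export
survival_sim_config <- function(n_samples = 300, n_signature_genes = 44,
                                true_hr = 1.83, baseline_hazard = 1 / 1000,
                                censor_rate = 1 / 2500,
                                arms = c(bortezomib = 0.5, dexamethasone = 0.5),
                                noise_sd = 1, seed = 1) {
  if (n_samples < 2 || n_signature_genes < 1) stopf("counts must be positive")
  if (true_hr <= 0) stopf("true_hr must be > 0")
  if (baseline_hazard <= 0 || censor_rate < 0) stopf("rates must be non-negative")
  if (abs(sum(arms) - 1) > 1e-8 || any(arms < 0)) stopf("arm proportions must sum to 1")
  structure(list(n_samples = n_samples, n_signature_genes = n_signature_genes,
                 true_hr = true_hr, baseline_hazard = baseline_hazard,
                 censor_rate = censor_rate, arms = arms, noise_sd = noise_sd,
                 seed = seed),
            class = "survival_sim_config")
}

#' Simulate an expression + outcome cohort linked to a signature
#'
#' @param config a [survival_sim_config()].
#' @return A list with `expression` (sample x gene matrix over signature
#'   genes), `survival` (data.frame: sample_id, time_days, event, arm),
#'   `true_high` (logical planted high-risk half) and the `config`.
#' @export
simulate_survival_cohort <- function(config) {
  if (!inherits(config, "survival_sim_config")) stopf("config must be a survival_sim_config")
  set.seed(config$seed)
  n <- config$n_samples
  k <- config$n_signature_genes
  sample_ids <- sprintf("S%04d", seq_len(n))
  score <- rnorm(n)
  expr <- matrix(score, n, k) + matrix(rnorm(n * k, 0, config$noise_sd), n, k)
  dimnames(expr) <- list(sample_ids, sprintf("SIG%03d", seq_len(k)))
  high <- rank(score, ties.method = "first") > n / 2
  hazard <- config$baseline_hazard * ifelse(high, config$true_hr, 1)
  t_event <- rexp(n, hazard)
  t_cens <- if (config$censor_rate > 0) rexp(n, config$censor_rate) else rep(Inf, n)
  arm <- sample(names(config$arms), n, replace = TRUE, prob = config$arms)
  surv <- data.frame(sample_id = sample_ids,
                     time_days = pmin(t_event, t_cens),
                     event = as.integer(t_event <= t_cens),
                     arm = arm, stringsAsFactors = FALSE)
  list(expression = expr, survival = surv,
       true_high = setNames(high, sample_ids), config = config)
}
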