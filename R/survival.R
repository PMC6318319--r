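# Survival stratification of an external expression cohort by a gene
# signature: collapse multi-probe genes by mean intensity, mean-center and
# scale per gene, dichotomize samples into high/low signature groups by
# K-means (Hartigan-Wong), then compare overall survival by Kaplan-Meier
# curves, the Mantel-Cox log-rank test, and hazard ratios (Cox partial
# likelihood with Efron ties; a Mantel-Haenszel O/E-based HR is reported
# alongside).

#' Collapse probe-level intensities to gene level
#'
#' For genes with multiple probe sets, mean intensities are computed;
#' probes absent from the map are dropped with a warning.
#'
#' @param intensities sample x probe matrix with dimnames.
#' @param probe_map data.frame with columns `probe_id`, `gene_id` (each
#'   probe maps to at most one gene).
#' @return sample x gene matrix.
#' @export
collapse_probes <- function(intensities, probe_map) {
  if (anyDuplicated(probe_map$probe_id)) stopf("a probe maps to more than one gene")
  probes <- colnames(intensities)
  mapped <- probes %in% probe_map$probe_id
  if (any(!mapped))
    warnf("dropping %d unmapped probe(s): %s", sum(!mapped),
          paste(head(probes[!mapped], 5), collapse = ", "))
  probes <- probes[mapped]
  gene_of <- setNames(probe_map$gene_id, probe_map$probe_id)[probes]
  genes <- unique(gene_of)
  out <- vapply(genes, function(g) {
    rowMeans(intensities[, probes[gene_of == g], drop = FALSE])
  }, numeric(nrow(intensities)))
  dimnames(out) <- list(rownames(intensities), genes)
  out
}

#' Mean-center and scale columns to unit variance
#'
#' Each gene column ends with mean 0 and sd 1; zero-variance genes become
#' all-zero columns with a warning.
#'
#' @param m sample x gene matrix (needs >= 2 samples).
#' @return The standardized matrix.
#' @export
standardize <- function(m) {
  if (nrow(m) < 2) stopf("need at least 2 samples")
  mu <- colMeans(m)
  s <- col_sds(m)
  zero <- s == 0
  if (any(zero)) {
    warnf("%d zero-variance gene column(s) set to zero: %s", sum(zero),
          paste(head(colnames(m)[zero], 5), collapse = ", "))
    s[zero] <- 1
  }
  out <- sweep(sweep(m, 2, mu, "-"), 2, s, "/")
  out[, zero] <- 0
  out
}

#' Dichotomize samples into high/low signature groups by K-means
#'
#' Hartigan-Wong K-means on the (standardized) signature-gene submatrix,
#' best of `n_restarts` starts by within-cluster sum of squares. The
#' cluster with the larger mean signature score is labeled "high", so the
#' labels do not depend on the seed.
#'
#' @param scores sample x signature-gene numeric matrix.
#' @param k number of clusters (default 2).
#' @param n_restarts random restarts (default 25).
#' @param seed random seed for the restarts.
#' @return A `risk_groups` list: `label_of_sample` (named "high"/"low"),
#'   `cluster_means` (mean score per label), `kmeans` (the fit).
#' @export
kmeans_dichotomize <- function(scores, k = 2, n_restarts = 25, seed = 1) {
  if (!is.matrix(scores)) scores <- as.matrix(scores)
  if (k > nrow(scores)) stopf("k exceeds the number of samples")
  set.seed(seed)
  km <- kmeans(scores, centers = k, nstart = n_restarts,
               algorithm = "Hartigan-Wong")
  score <- rowMeans(scores)
  cl_mean <- tapply(score, km$cluster, mean)
  if (k == 2) {
    labels <- ifelse(km$cluster == as.integer(names(which.max(cl_mean))),
                     "high", "low")
  } else {
    ord <- order(cl_mean)
    labels <- paste0("C", match(km$cluster, as.integer(names(cl_mean)[ord])))
  }
  lab_means <- tapply(score, labels, mean)
  structure(list(label_of_sample = setNames(labels, rownames(scores)),
                 cluster_means = lab_means,
                 kmeans = km),
            class = "risk_groups")
}

# normalize a grouping argument for the survival tests
sample_groups <- function(records, groups) {
  if (inherits(groups, "risk_groups")) groups <- groups$label_of_sample
  if (!is.null(names(groups))) {
    missing <- setdiff(records$sample_id, names(groups))
    if (length(missing) > 0)
      stopf("no group for sample(s): %s", paste(head(missing, 5), collapse = ", "))
    groups <- groups[records$sample_id]
  }
  factor(as.character(groups))
}

#' Kaplan-Meier product-limit estimate per group
#'
#' @param records data.frame with `sample_id`, `time_days`, `event` (1 =
#'   death observed, 0 = censored).
#' @param groups a `risk_groups`, or named label vector; omit for a single
#'   pooled curve.
#' @return Named list of per-group data.frames with columns `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival` (rows at event times,
#'   right-continuous steps).
#' @export
km_estimate <- function(records, groups = NULL) {
  if (any(records$time_days < 0)) stopf("negative survival times")
  g <- if (is.null(groups)) factor(rep("all", nrow(records)))
       else sample_groups(records, groups)
  out <- lapply(levels(g), function(lv) {
    d <- records[g == lv, , drop = FALSE]
    times <- sort(unique(d$time_days))
    surv <- 1
    rows <- lapply(times, function(t) {
      n_risk <- sum(d$time_days >= t)
      n_event <- sum(d$time_days == t & d$event == 1)
      n_censor <- sum(d$time_days == t & d$event == 0)
      if (n_event > 0) surv <<- surv * (1 - n_event / n_risk)
      data.frame(time = t, n_risk = n_risk, n_event = n_event,
                 n_censor = n_censor, survival = surv)
    })
    do.call(rbind, rows)
  })
  names(out) <- levels(g)
  out
}

#' Mantel-Cox log-rank test between two groups
#'
#' Sum of observed minus expected events over event times with the
#' hypergeometric variance; p from chi-square with 1 df.
#'
#' @inheritParams km_estimate
#' @return A `logrank_result` list: `chi_square`, `p`, `observed`,
#'   `expected` (per group), `n` (per group).
#' @export
logrank_test <- function(records, groups) {
  g <- sample_groups(records, groups)
  if (nlevels(g) != 2) stopf("log-rank comparison requires exactly 2 groups")
  if (any(table(g) == 0)) stopf("empty group")
  if (sum(records$event) < 1) stopf("need at least one event")
  fit <- survdiff(Surv(records$time_days, records$event) ~ g)
  p <- pchisq(fit$chisq, df = 1, lower.tail = FALSE)
  structure(list(chi_square = unname(fit$chisq), p = p,
                 observed = setNames(fit$obs, levels(g)),
                 expected = setNames(fit$exp, levels(g)),
                 n = setNames(as.vector(fit$n), levels(g))),
            class = "logrank_result")
}

#' Hazard ratio between two groups
#'
#' Cox proportional-hazards fit with the single binary covariate (high vs
#' low), Efron tie handling; HR = exp(coef) with a Wald 95% CI. A
#' Mantel-Haenszel O/E-based HR from the log-rank tabulation is reported
#' alongside.
#'
#' @inheritParams km_estimate
#' @param high_label the label treated as the exposed group (default
#'   "high").
#' @return A `cox_result` list: `hr`, `ci_low`, `ci_high`, `log_hr_se`,
#'   `p_wald`, `hr_mantel_haenszel`.
#' @export
hazard_ratio <- function(records, groups, high_label = "high") {
  g <- sample_groups(records, groups)
  if (nlevels(g) != 2) stopf("hazard ratio requires exactly 2 groups")
  if (!high_label %in% levels(g)) stopf("no group labeled %s", high_label)
  events_per_group <- tapply(records$event, g, sum)
  if (any(events_per_group == 0))
    stopf("no events in group %s (monotone likelihood)",
          names(events_per_group)[events_per_group == 0][1])
  x <- as.integer(g == high_label)
  fit <- coxph(Surv(records$time_days, records$event) ~ x, ties = "efron")
  coef <- unname(fit$coefficients)
  se <- sqrt(unname(fit$var[1, 1]))
  sd_fit <- survdiff(Surv(records$time_days, records$event) ~ g)
  oe <- fit_oe_ratio(sd_fit, levels(g), high_label)
  structure(list(hr = exp(coef),
                 ci_low = exp(coef - 1.96 * se),
                 ci_high = exp(coef + 1.96 * se),
                 log_hr_se = se,
                 p_wald = pchisq((coef / se)^2, 1, lower.tail = FALSE),
                 hr_mantel_haenszel = oe),
            class = "cox_result")
}

fit_oe_ratio <- function(sd_fit, lvls, high_label) {
  hi <- which(lvls == high_label)
  lo <- setdiff(seq_along(lvls), hi)
  (sd_fit$obs[hi] / sd_fit$exp[hi]) / (sd_fit$obs[lo] / sd_fit$exp[lo])
}

#' Signature-based survival stratification (one-call wrapper)
#'
#' Collapses probes (when a map is given), standardizes, restricts to the
#' signature genes, K-means-dichotomizes, and runs the Kaplan-Meier,
#' log-rank and hazard-ratio comparisons; optionally per treatment arm.
#'
#' @param intensities sample x probe (or sample x gene) matrix.
#' @param records survival data.frame (`sample_id`, `time_days`, `event`,
#'   optional `arm`).
#' @param signature_genes character vector of signature gene ids.
#' @param probe_map optional probe-to-gene map data.frame.
#' @param arm optional arm label; when given, samples are filtered to that
#'   arm before testing.
#' @param max_missing_fraction drop samples missing more than this
#'   fraction of signature genes (default 0.2).
#' @param n_restarts,seed K-means settings.
#' @return A `survival_stratification` list: `risk_groups`, `km`,
#'   `logrank`, `cox`, `n_samples`, `signature_genes_used`.
#' @export
stratify_survival <- function(intensities, records, signature_genes,
                              probe_map = NULL, arm = NULL,
                              max_missing_fraction = 0.2,
                              n_restarts = 25, seed = 1) {
  m <- if (!is.null(probe_map)) collapse_probes(intensities, probe_map) else intensities
  found <- intersect(signature_genes, colnames(m))
  if (length(found) == 0) stopf("no signature genes found in the matrix")
  if (length(found) < length(signature_genes))
    warnf("%d of %d signature genes absent from the matrix",
          length(signature_genes) - length(found), length(signature_genes))
  miss_frac <- rowMeans(is.na(m[, found, drop = FALSE]))
  keep <- miss_frac <= max_missing_fraction
  if (any(!keep))
    warnf("dropping %d sample(s) missing > %d%% of signature genes",
          sum(!keep), round(100 * max_missing_fraction))
  m <- m[keep, , drop = FALSE]
  if (anyNA(m[, found])) {
    for (gcol in found) {                   # mean-impute the few remaining
      col <- m[, gcol]
      col[is.na(col)] <- mean(col, na.rm = TRUE)
      m[, gcol] <- col
    }
  }
  z <- standardize(m[, found, drop = FALSE])
  recs <- records[records$sample_id %in% rownames(z), , drop = FALSE]
  if (!is.null(arm)) {
    if (!"arm" %in% names(recs)) stopf("records have no arm column")
    recs <- recs[recs$arm == arm, , drop = FALSE]
  }
  z <- z[recs$sample_id, , drop = FALSE]
  rg <- kmeans_dichotomize(z, n_restarts = n_restarts, seed = seed)
  structure(list(risk_groups = rg,
                 km = km_estimate(recs, rg),
                 logrank = logrank_test(recs, rg),
                 cox = hazard_ratio(recs, rg),
                 n_samples = nrow(recs),
                 signature_genes_used = found,
                 arm = arm),
            class = "survival_stratification")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank: chi-square = %.3f, p = %.3g\n", x$chi_square, x$p))
  invisible(x)
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox HR = %.3f (95%% CI %.3f-%.3f); Mantel-Haenszel HR = %.3f\n",
              x$hr, x$ci_low, x$ci_high, x$hr_mantel_haenszel))
  invisible(x)
}

#' @export
print.survival_stratification <- function(x, ...) {
  cat(sprintf("survival stratification%s: n = %d\n",
              if (is.null(x$arm)) "" else paste0(" (arm ", x$arm, ")"),
              x$n_samples))
  print(x$logrank); print(x$cox)
  invisible(x)
}
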