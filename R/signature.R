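# Group-wise differential expression and signature derivation: per-gene
# one-way fixed-effects ANOVA across the ordered groups (log2 scale),
# pairwise fold-change screening (FC computed as 2^(difference of group
# mean log2 values), i.e. a geometric-mean ratio), the common up-regulated
# set (passing FC >= fc_min and p < p_max in every comparison against the
# reference group), the adjacent-group monotone signature (passing in every
# adjacent comparison, intersected with the common set), and hypergeometric
# gene-set over-representation.

# vectorized per-group means of a genes x cells matrix
group_means <- function(m, g) {
  mm <- vapply(levels(g), function(lv) rowMeans(m[, g == lv, drop = FALSE]),
               numeric(nrow(m)))
  matrix(mm, nrow = nrow(m), dimnames = list(rownames(m), levels(g)))
}

#' Per-gene one-way ANOVA across groups
#'
#' Fixed-effects one-way ANOVA on log2(TPM+1) values; F and p come from the
#' F distribution with (k-1, n-k) degrees of freedom. A gene with zero
#' between-group sum of squares gets F = 0, p = 1.
#'
#' @param expr log2 matrix (genes x cells) or `expression_matrix`.
#' @param groups a `group_assignment`, factor, or named label vector.
#' @return data.frame: `gene_id`, one `mean_<label>` column per group,
#'   `anova_F`, `anova_p`.
#' @export
anova_per_gene <- function(expr, groups) {
  m <- as_log_matrix(expr)
  g <- as_group_factor(groups, colnames(m))
  if (nlevels(g) < 2) stopf("need at least 2 groups")
  sizes <- table(g)
  if (any(sizes < 2)) stopf("group(s) with fewer than 2 cells: %s",
                            paste(names(sizes)[sizes < 2], collapse = ", "))
  n <- ncol(m); k <- nlevels(g)
  gm <- group_means(m, g)
  grand <- rowMeans(m)
  ssb <- as.vector((gm^2) %*% as.vector(sizes)) - n * grand^2
  sst <- rowSums(m^2) - n * grand^2
  ssw <- pmax(sst - ssb, 0)
  ssb <- pmax(ssb, 0)
  F <- (ssb / (k - 1)) / (ssw / (n - k))
  F[ssb <= 1e-12] <- 0                      # no between-group signal
  p <- pf(F, k - 1, n - k, lower.tail = FALSE)
  out <- data.frame(gene_id = rownames(m), stringsAsFactors = FALSE)
  for (lv in levels(g)) out[[paste0("mean_", lv)]] <- gm[, lv]
  out$anova_F <- F
  out$anova_p <- p
  out
}

#' Pairwise log2 fold changes and p-values between groups
#'
#' For each requested comparison (a, b): log2 FC = mean_log(b) -
#' mean_log(a), so FC >= 2 corresponds to log2 FC >= 1; the p-value is the
#' two-group one-way ANOVA (pooled-variance t) on log2 values.
#'
#' @param expr log2 matrix or `expression_matrix`.
#' @param groups group labels (see [anova_per_gene()]).
#' @param comparisons list of length-2 character vectors `c(a, b)`.
#' @return Long data.frame: `gene_id`, `group_a`, `group_b`, `log2_fc`,
#'   `p`.
#' @export
pairwise_fc <- function(expr, groups, comparisons) {
  m <- as_log_matrix(expr)
  g <- as_group_factor(groups, colnames(m))
  out <- lapply(comparisons, function(cmp) {
    a <- cmp[1]; b <- cmp[2]
    if (!all(c(a, b) %in% levels(g)))
      stopf("unknown group in comparison %s vs %s", a, b)
    ia <- g == a; ib <- g == b
    na <- sum(ia); nb <- sum(ib)
    if (na < 2 || nb < 2) stopf("group with fewer than 2 cells in %s vs %s", a, b)
    ma <- rowMeans(m[, ia, drop = FALSE]); mb <- rowMeans(m[, ib, drop = FALSE])
    va <- row_sds(m[, ia, drop = FALSE])^2; vb <- row_sds(m[, ib, drop = FALSE])^2
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    tstat <- ifelse(se > 0, (mb - ma) / se, ifelse(mb == ma, 0, Inf))
    p <- pf(tstat^2, 1, na + nb - 2, lower.tail = FALSE)
    p[se == 0 & mb == ma] <- 1
    data.frame(gene_id = rownames(m), group_a = a, group_b = b,
               log2_fc = mb - ma, p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# gene ids passing log2 FC >= log2(fc_min) and p < p_max in every listed
# comparison of a pairwise_fc table
pass_all_comparisons <- function(pw, fc_min, p_max) {
  pw$pass <- pw$log2_fc >= log2(fc_min) & pw$p < p_max
  keys <- paste(pw$group_a, pw$group_b)
  Reduce(intersect, lapply(split(pw, keys), function(d) d$gene_id[d$pass]))
}

#' Common up-regulated gene set versus a reference group
#'
#' Intersection over all non-reference groups g of the genes with
#' log2 FC(g vs reference) >= log2(fc_min) and p < p_max.
#'
#' @param expr log2 matrix or `expression_matrix`.
#' @param groups group labels.
#' @param reference reference group label (default "L1").
#' @param fc_min fold-change cutoff on the linear scale (default 2;
#'   inclusive, so FC exactly 2 passes).
#' @param p_max p-value cutoff (strict <; default 0.05).
#' @return Character vector of gene ids.
#' @export
common_upregulated <- function(expr, groups, reference = "L1",
                               fc_min = 2, p_max = 0.05) {
  g <- as_group_factor(groups, colnames(as_log_matrix(expr)))
  others <- setdiff(levels(g), reference)
  if (!reference %in% levels(g)) stopf("reference group %s not present", reference)
  if (length(others) == 0) stopf("need at least one non-reference group")
  pw <- pairwise_fc(expr, groups, lapply(others, function(o) c(reference, o)))
  pass_all_comparisons(pw, fc_min, p_max)
}

#' Adjacent-group monotone progression signature
#'
#' Genes passing log2 FC >= log2(fc_min) and p < p_max in EVERY adjacent
#' comparison (L1 vs L2, L2 vs L3, ...), intersected with the common
#' up-regulated set versus the reference, yielding the consistently
#' increasing progression signature.
#'
#' @inheritParams common_upregulated
#' @return A `signature_result` list: `common_up`, `adjacent_monotone`,
#'   `thresholds`, and the pairwise tables (`pairwise_reference`,
#'   `pairwise_adjacent`).
#' @export
adjacent_monotone_signature <- function(expr, groups, reference = "L1",
                                        fc_min = 2, p_max = 0.05) {
  g <- as_group_factor(groups, colnames(as_log_matrix(expr)))
  lv <- levels(g)
  if (length(lv) < 3) stopf("need at least 3 ordered groups")
  others <- setdiff(lv, reference)
  pw_ref <- pairwise_fc(expr, groups, lapply(others, function(o) c(reference, o)))
  adj <- lapply(seq_len(length(lv) - 1), function(i) c(lv[i], lv[i + 1]))
  pw_adj <- pairwise_fc(expr, groups, adj)
  common <- pass_all_comparisons(pw_ref, fc_min, p_max)
  mono <- intersect(pass_all_comparisons(pw_adj, fc_min, p_max), common)
  structure(list(common_up = common,
                 adjacent_monotone = mono,
                 thresholds = c(fc_min = fc_min, p_max = p_max),
                 pairwise_reference = pw_ref,
                 pairwise_adjacent = pw_adj),
            class = "signature_result")
}

#' Hypergeometric gene-set over-representation
#'
#' For each set, the upper-tail hypergeometric probability
#' P(X >= overlap) with X ~ Hypergeom(universe_size, |set|, |query|), plus
#' Benjamini-Hochberg q-values across the collection.
#'
#' @param query character vector of query gene ids.
#' @param collection named list of gene sets (e.g. from [read_gmt()]).
#' @param universe_size declared universe size (genes tested).
#' @param universe optional explicit universe; when given, query and sets
#'   are intersected with it and `universe_size` defaults to its length.
#' @return data.frame: `set_name`, `set_size`, `query_size`, `overlap`,
#'   `universe_size`, `p`, `q`, sorted by p.
#' @export
geneset_overlap <- function(query, collection, universe_size = NULL,
                            universe = NULL) {
  if (!is.null(universe)) {
    query <- intersect(query, universe)
    collection <- lapply(collection, intersect, universe)
    universe_size <- universe_size %||% length(universe)
  }
  if (is.null(universe_size)) stopf("universe_size (or universe) is required")
  query <- unique(query)
  if (length(query) > universe_size) stopf("query larger than universe")
  res <- lapply(names(collection), function(nm) {
    set <- unique(collection[[nm]])
    if (length(set) > universe_size)
      stopf("set %s larger than the declared universe", nm)
    k <- length(intersect(query, set))
    p <- phyper(k - 1, length(set), universe_size - length(set),
                length(query), lower.tail = FALSE)
    data.frame(set_name = nm, set_size = length(set),
               query_size = length(query), overlap = k,
               universe_size = universe_size, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}

#' Group-wise expression report for a supplied gene list
#'
#' Reporting view over [anova_per_gene()] and [pairwise_fc()] restricted to
#' a gene list of interest (e.g. proteasome subunits or unfolded-protein-
#' response genes): per-group means, global ANOVA, and the adjacent and
#' reference-based fold changes. Unknown genes are dropped with a warning.
#'
#' @inheritParams common_upregulated
#' @param gene_list genes to report on.
#' @return data.frame merging the ANOVA table with wide-format
#'   `fc_<a>_vs_<b>` / `p_<a>_vs_<b>` columns; empty for an empty list.
#' @export
geneset_group_report <- function(expr, groups, gene_list, reference = "L1") {
  m <- as_log_matrix(expr)
  gene_list <- unique(gene_list)
  unknown <- setdiff(gene_list, rownames(m))
  if (length(unknown) > 0) {
    warnf("dropping %d unknown gene(s): %s", length(unknown),
          paste(head(unknown, 5), collapse = ", "))
    gene_list <- setdiff(gene_list, unknown)
  }
  if (length(gene_list) == 0) {
    return(data.frame(gene_id = character(0)))
  }
  msub <- m[gene_list, , drop = FALSE]
  g <- as_group_factor(groups, colnames(m))
  lv <- levels(g)
  de <- anova_per_gene(msub, groups)
  cmps <- c(lapply(setdiff(lv, reference), function(o) c(reference, o)),
            lapply(seq_len(length(lv) - 1), function(i) c(lv[i], lv[i + 1])))
  cmps <- unique(cmps)
  pw <- pairwise_fc(msub, groups, cmps)
  for (key in unique(paste(pw$group_a, pw$group_b))) {
    d <- pw[paste(pw$group_a, pw$group_b) == key, ]
    tag <- sub(" ", "_vs_", key, fixed = TRUE)
    de[[paste0("log2fc_", tag)]] <- d$log2_fc[match(de$gene_id, d$gene_id)]
    de[[paste0("p_", tag)]] <- d$p[match(de$gene_id, d$gene_id)]
  }
  de
}

#' @export
print.signature_result <- function(x, ...) {
  cat(sprintf("signature_result: %d common up-regulated, %d adjacent-monotone (FC >= %g, p < %g)\n",
              length(x$common_up), length(x$adjacent_monotone),
              x$thresholds["fc_min"], x$thresholds["p_max"]))
  invisible(x)
}
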