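# Unsupervised cell clustering: 1 - Pearson correlation distance between
# cells over the selected genes, agglomeration under the Ward.D2 criterion
# (Lance-Williams recurrence on squared dissimilarities, square-root merge
# heights -- the Murtagh-Legendre formulation that the name "Ward.D2"
# denotes), a k-group cut, and relabeling of groups in ascending order of
# mean expression so that L1 is always the lowest-expressing group.

#' 1 - Pearson correlation distance between cells
#'
#' @param expr log2(TPM+1) matrix restricted to the selected genes
#'   (genes x cells), or an `expression_matrix` plus `genes`.
#' @param genes optional gene subset to use.
#' @return A `dist` object over cells with entries `1 - r` in \[0, 2\].
#' @export
pearson_distance <- function(expr, genes = NULL) {
  m <- as_log_matrix(expr)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing) > 0)
      stopf("gene(s) not in matrix: %s", paste(head(missing, 5), collapse = ", "))
    m <- m[genes, , drop = FALSE]
  }
  if (ncol(m) < 2) stopf("need at least 2 cells")
  sds <- col_sds(m)
  if (any(sds == 0))
    stopf("zero-variance cell vector(s): %s",
          paste(head(colnames(m)[sds == 0], 5), collapse = ", "))
  as.dist(1 - cor(m))
}

#' Ward.D2 agglomerative clustering
#'
#' Implements the Ward.D2 criterion by the Lance-Williams recurrence on
#' squared dissimilarities, reporting square-root heights. Ties in the
#' merge criterion are broken by the lexicographically smallest pair of
#' active cluster slots, making the merge sequence deterministic across
#' platforms. The result is a valid `hclust` object (also classed
#' `ward_dendrogram`), so standard tools (`cutree`, `plot`) apply.
#'
#' @param dist a `dist` object or symmetric distance matrix.
#' @return An object of class `c("ward_dendrogram", "hclust")`.
#' @export
ward_linkage <- function(dist) {
  D <- as.matrix(dist)
  if (nrow(D) < 2) stopf("need at least 2 observations")
  if (any(abs(D - t(D)) > 1e-12)) stopf("distance matrix must be symmetric")
  labels <- rownames(D) %||% as.character(seq_len(nrow(D)))
  n <- nrow(D)
  D <- D^2                       # work on squared dissimilarities
  diag(D) <- Inf
  alive <- rep(TRUE, n)
  size <- rep(1, n)
  slot_id <- -seq_len(n)         # hclust convention: negatives = singletons
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    Dv <- D
    Dv[!alive, ] <- Inf
    Dv[, !alive] <- Inf
    Dv[lower.tri(Dv, diag = TRUE)] <- Inf
    best <- min(Dv)
    cand <- which(Dv == best, arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]

    height[step] <- sqrt(best)
    pair <- sort(c(slot_id[i], slot_id[j]))
    merge[step, ] <- if (pair[1] < 0 && pair[2] < 0) rev(pair) else pair

    ks <- which(alive); ks <- ks[ks != i & ks != j]
    if (length(ks) > 0) {
      dk <- ((size[i] + size[ks]) * pmin(D[i, ks], D[ks, i]) +
             (size[j] + size[ks]) * pmin(D[j, ks], D[ks, j]) -
             size[ks] * best) / (size[i] + size[j] + size[ks])
      D[i, ks] <- dk; D[ks, i] <- dk
    }
    size[i] <- size[i] + size[j]
    alive[j] <- FALSE
    slot_id[i] <- step
  }

  structure(list(merge = merge, height = height,
                 order = dendrogram_order(merge),
                 labels = labels, method = "ward.D2",
                 dist.method = "1 - Pearson correlation",
                 call = match.call()),
            class = c("ward_dendrogram", "hclust"))
}

# leaf order for plotting: left-to-right traversal of the merge list
dendrogram_order <- function(merge) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(nrow(merge))
}

#' Cut a dendrogram into k groups
#'
#' The partition obtained by removing the k-1 highest merges; with a
#' monotone linkage (Ward.D2 on a valid distance) this equals keeping the
#' first n-k merges of the agglomeration.
#'
#' @param dendrogram a `ward_dendrogram`/`hclust` object.
#' @param k number of groups, between 1 and the number of leaves.
#' @return Integer vector of group codes (arbitrary order) named by leaf.
#' @export
cut_tree <- function(dendrogram, k) {
  n <- length(dendrogram$labels)
  if (k < 1 || k > n) stopf("k must be in 1..%d", n)
  comp <- -seq_len(n)                       # component id per leaf
  names(comp) <- dendrogram$labels
  if (n - k >= 1) {
    for (step in seq_len(n - k)) {
      m <- dendrogram$merge[step, ]
      members <- comp %in% m
      comp[members] <- step
    }
  }
  match(comp, unique(comp))
}

#' Order cluster labels by expression level
#'
#' Relabels a raw partition as L1..Lk in ascending order of the per-group
#' mean (over cells) of mean log2(TPM+1) over the ordering genes, so that
#' L1 is the lowest-expressing group. Ties are broken by group size
#' (descending), then by the lexicographically smallest member cell id.
#'
#' @param partition integer/character vector of raw group codes named by
#'   cell id (e.g. from [cut_tree()]).
#' @param expr log2 matrix or `expression_matrix` covering the cells.
#' @param ordering_genes genes whose mean expression orders the groups
#'   (default: all genes in `expr` -- in the pipeline, the selected genes).
#' @return A `group_assignment` list: `label_of_cell` (named "L1".."Lk"),
#'   `k`, `ordering_statistic` (per-label mean).
#' @export
order_groups <- function(partition, expr, ordering_genes = NULL) {
  m <- as_log_matrix(expr)
  if (is.null(names(partition))) stopf("partition must be named by cell id")
  if (!all(names(partition) %in% colnames(m))) stopf("partition cells missing from expr")
  m <- m[, names(partition), drop = FALSE]
  if (!is.null(ordering_genes)) m <- m[ordering_genes, , drop = FALSE]
  if (nrow(m) == 0) stopf("ordering_genes is empty")
  groups <- unique(partition)
  if (any(!table(partition) > 0)) stopf("empty group")
  cell_score <- colMeans(m)
  stat <- vapply(groups, function(g) mean(cell_score[partition == g]), 0)
  sizes <- vapply(groups, function(g) sum(partition == g), 0)
  first_id <- vapply(groups, function(g) min(names(partition)[partition == g]), "")
  ord <- order(stat, -sizes, first_id)
  labels <- paste0("L", seq_along(groups))
  map <- setNames(labels, as.character(groups[ord]))
  structure(list(label_of_cell = setNames(unname(map[as.character(partition)]),
                                          names(partition)),
                 k = length(groups),
                 ordering_statistic = setNames(stat[ord], labels)),
            class = "group_assignment")
}

#' Cluster cells into ordered groups (one-call wrapper)
#'
#' Runs [pearson_distance()], [ward_linkage()], [cut_tree()] and
#' [order_groups()] in sequence.
#'
#' @param expr `expression_matrix` or log2 matrix.
#' @param genes selected genes to cluster on.
#' @param k group count (default 4).
#' @return A `group_assignment` with the dendrogram attached as
#'   `$dendrogram`.
#' @export
cluster_cells <- function(expr, genes = NULL, k = 4) {
  d <- pearson_distance(expr, genes)
  dend <- ward_linkage(d)
  part <- cut_tree(dend, k)
  names(part) <- dend$labels
  ga <- order_groups(part, expr, ordering_genes = genes)
  ga$dendrogram <- dend
  ga
}

#' @export
print.group_assignment <- function(x, ...) {
  tab <- table(x$label_of_cell)
  cat(sprintf("group_assignment: %d cells in %d ordered groups\n",
              length(x$label_of_cell), x$k))
  print(tab)
  invisible(x)
}
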