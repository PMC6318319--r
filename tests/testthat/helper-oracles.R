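# Independent oracles used to check the implementation by a second route,
# plus small fixture builders. Oracles deliberately recompute everything
# from first principles (loops, enumeration) and share no code with R/.

# Build an expression_matrix directly from a TPM matrix (for hand toys
# where exact TPM values are needed).
expr_from_tpm <- function(tpm) {
  structure(list(tpm = tpm, log2_tpm1 = log2(tpm + 1),
                 gene_ids = rownames(tpm), cell_ids = colnames(tpm),
                 patient_of_cell = NULL),
            class = "expression_matrix")
}

# Exhaustive greedy Ward clustering computed from raw Euclidean
# coordinates: at each step merge the cluster pair minimizing
# 2 * |A||B|/(|A|+|B|) * ||centroid_A - centroid_B||^2, recomputed from the
# points; height is the square root of that cost.
oracle_ward_points <- function(X) {
  n <- nrow(X)
  members <- lapply(seq_len(n), identity)
  slot_id <- -seq_len(n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(members)) for (j in seq_along(members)) if (i < j) {
      A <- members[[i]]; B <- members[[j]]
      ca <- colMeans(X[A, , drop = FALSE]); cb <- colMeans(X[B, , drop = FALSE])
      cost <- 2 * length(A) * length(B) / (length(A) + length(B)) * sum((ca - cb)^2)
      if (cost < best - 1e-12) { best <- cost; bi <- i; bj <- j }
    }
    pair <- sort(c(slot_id[bi], slot_id[bj]))
    merge[step, ] <- if (pair[1] < 0 && pair[2] < 0) rev(pair) else pair
    height[step] <- sqrt(best)
    members[[bi]] <- c(members[[bi]], members[[bj]])
    members[[bj]] <- NULL
    slot_id[bi] <- step
    slot_id <- slot_id[-bj]
  }
  list(merge = merge, height = height)
}

# One-way fixed-effects ANOVA by explicit sum-of-squares decomposition.
oracle_anova <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups); n <- length(values)
  grand <- mean(values)
  ssb <- 0; ssw <- 0
  for (lv in levels(groups)) {
    v <- values[groups == lv]
    ssb <- ssb + length(v) * (mean(v) - grand)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  F <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = F, p = pf(F, k - 1, n - k, lower.tail = FALSE))
}

# Hypergeometric upper tail by exhaustive enumeration of all query-sized
# subsets of the universe (feasible for universe <= 12).
oracle_hyper <- function(universe_size, set_size, query_size, overlap) {
  subsets <- combn(universe_size, query_size)
  hits <- apply(subsets, 2, function(s) sum(s <= set_size) >= overlap)
  mean(hits)
}

# Mantel-Cox log-rank by direct O/E/V tabulation over event times.
oracle_logrank <- function(time, event, group) {
  g1 <- group == levels(factor(group))[1]
  O1 <- 0; E1 <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O1 - E1)^2 / V
  list(chi_square = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# Shared small simulation configs. The 4 x 40-cell balanced design is the
# planted world used by the recovery checks (one patient per group).
balanced_sim_config <- function(seed, delta_log2 = 1.5) {
  sim_config(n_patients = 4, cells_per_patient = c(40, 40),
             group_mixture = diag(4), delta_log2 = delta_log2, seed = seed)
}

# Convenience: run selection on a simulated dataset with truth flags.
run_selection <- function(ds) {
  expr <- tpm_from_counts(ds)
  stats <- compute_gene_stats(expr, hk_list = ds$true_housekeeping_genes)
  list(expr = expr, stats = stats, selection = select_variable_genes(stats))
}
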