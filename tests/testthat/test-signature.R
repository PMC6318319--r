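toy_groups <- function(m, labels) setNames(labels, colnames(m))

test_that("per-gene ANOVA matches the sum-of-squares oracle", {
  # 3-group toy
  m <- matrix(c(1, 2, 3, 2, 3, 4, 4, 5, 6), 1)
  colnames(m) <- paste0("c", 1:9)
  rownames(m) <- "g1"
  g <- toy_groups(m, rep(c("L1", "L2", "L3"), each = 3))
  de <- anova_per_gene(m, g)
  o <- oracle_anova(m[1, ], rep(c("L1", "L2", "L3"), each = 3))
  expect_equal(de$anova_F, o$F, tolerance = 1e-12)
  expect_equal(de$anova_p, o$p, tolerance = 1e-12)
  expect_equal(de$mean_L1, 2)
  expect_equal(de$mean_L3, 5)
  # random small instances, 100 seeds
  for (s in 1:100) {
    set.seed(s)
    k <- sample(2:5, 1)
    sizes <- sample(2:10, k, replace = TRUE)
    vals <- rnorm(sum(sizes), sd = 2)
    grp <- rep(paste0("L", seq_len(k)), sizes)
    mm <- matrix(vals, 1, dimnames = list("g", paste0("c", seq_along(vals))))
    de <- anova_per_gene(mm, setNames(grp, colnames(mm)))
    o <- oracle_anova(vals, grp)
    expect_equal(de$anova_F, o$F, tolerance = 1e-10)
    expect_equal(de$anova_p, o$p, tolerance = 1e-10)
  }
})

test_that("two-group F equals the squared pooled t statistic", {
  for (s in 1:20) {
    set.seed(s)
    x <- rnorm(8); y <- rnorm(6, mean = 0.5)
    mm <- matrix(c(x, y), 1, dimnames = list("g", paste0("c", 1:14)))
    g <- setNames(rep(c("A", "B"), c(8, 6)), colnames(mm))
    de <- anova_per_gene(mm, g)
    tt <- t.test(y, x, var.equal = TRUE)
    expect_equal(de$anova_F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(de$anova_p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("constant genes give F = 0 and p = 1", {
  mm <- matrix(5, 1, 9, dimnames = list("g", paste0("c", 1:9)))
  g <- setNames(rep(c("L1", "L2", "L3"), each = 3), colnames(mm))
  de <- anova_per_gene(mm, g)
  expect_equal(de$anova_F, 0)
  expect_equal(de$anova_p, 1)
  expect_error(anova_per_gene(mm[, 1:4, drop = FALSE], setNames(c("A", "A", "A", "B"),
                                                  paste0("c", 1:4))),
               "fewer than 2")
})

test_that("pairwise fold changes match direct computation", {
  m <- rbind(up = c(3, 3.01, 2.99, 4, 4.01, 3.99),
             flat = c(2, 2.1, 1.9, 2, 2.05, 1.95))
  colnames(m) <- paste0("c", 1:6)
  g <- toy_groups(m, rep(c("L1", "L2"), each = 3))
  pw <- pairwise_fc(m, g, list(c("L1", "L2")))
  expect_equal(pw$log2_fc[pw$gene_id == "up"], 1)     # FC exactly 2
  t_up <- t.test(m["up", 4:6], m["up", 1:3], var.equal = TRUE)$p.value
  expect_equal(pw$p[pw$gene_id == "up"], t_up, tolerance = 1e-9)
  # identical group values: FC = 1 (log2 0) and p = 1
  m2 <- rbind(same = rep(c(1, 2, 3), 2))
  colnames(m2) <- paste0("c", 1:6)
  pw2 <- pairwise_fc(m2, toy_groups(m2, rep(c("A", "B"), 3)), list(c("A", "B")))
  expect_equal(pw2$log2_fc, 0)
  expect_error(pairwise_fc(m, g, list(c("L1", "LX"))), "unknown group")
})

test_that("common set requires every reference comparison to pass", {
  set.seed(1)
  noise <- function(n) rnorm(n, sd = 0.05)
  m <- rbind(both = c(1 + noise(3), 2.2 + noise(3), 2.4 + noise(3)),
             one = c(1 + noise(3), 2.2 + noise(3), 1.1 + noise(3)))
  colnames(m) <- paste0("c", 1:9)
  g <- toy_groups(m, rep(c("L1", "L2", "L3"), each = 3))
  common <- common_upregulated(m, g)
  expect_identical(common, "both")
  # a failing comparison empties the intersection
  m2 <- m
  m2["both", 7:9] <- 1 + noise(3)
  expect_length(common_upregulated(m2, g), 0)
})

test_that("monotone signature needs every adjacent step and nests in common", {
  set.seed(2)
  noise <- function(n) rnorm(n, sd = 0.05)
  m <- rbind(mono = c(1 + noise(4), 2.1 + noise(4), 3.2 + noise(4), 4.3 + noise(4)),
             jump = c(1 + noise(4), 2.1 + noise(4), 2.15 + noise(4), 4.3 + noise(4)))
  colnames(m) <- paste0("c", 1:16)
  g <- toy_groups(m, rep(paste0("L", 1:4), each = 4))
  sig <- adjacent_monotone_signature(m, g)
  expect_identical(sig$adjacent_monotone, "mono")   # flat L2->L3 step excludes jump
  expect_true("jump" %in% sig$common_up)
  expect_true(all(sig$adjacent_monotone %in% sig$common_up))
  expect_error(adjacent_monotone_signature(m[, 1:8], g[1:8]), "3 ordered groups")
})

test_that("signature recovery on planted data and emptiness under the null", {
  ds <- simulate_expression(balanced_sim_config(seed = 301))
  expr <- tpm_from_counts(ds)
  sig <- adjacent_monotone_signature(expr, setNames(paste0("L", ds$true_group),
                                                    ds$cell_ids))
  expect_gte(mean(ds$true_progression_genes %in% sig$adjacent_monotone), 0.9)
  expect_lte(mean(!sig$adjacent_monotone %in% ds$true_progression_genes), 0.05)
  # null world: no planted effect -> empty signature
  for (s in 1:3) {
    ds0 <- simulate_expression(balanced_sim_config(seed = 310 + s, delta_log2 = 0))
    sig0 <- adjacent_monotone_signature(tpm_from_counts(ds0),
                                        setNames(paste0("L", ds0$true_group),
                                                 ds0$cell_ids))
    expect_length(sig0$adjacent_monotone, 0)
  }
})

test_that("hypergeometric p matches exhaustive enumeration", {
  # universe 10, set 5, query 4, overlap 4 -> 5/210
  res <- geneset_overlap(query = paste0("g", 1:4),
                         collection = list(s = paste0("g", 1:5)),
                         universe_size = 10)
  expect_equal(res$p, 5 / 210, tolerance = 1e-12)
  expect_equal(res$p, oracle_hyper(10, 5, 4, 4), tolerance = 1e-12)
  # random enumeration checks for universes <= 12
  for (s in 1:20) {
    set.seed(s)
    N <- sample(5:12, 1)
    set_size <- sample(1:N, 1)
    query_size <- sample(1:N, 1)
    universe <- paste0("u", seq_len(N))
    set_genes <- universe[seq_len(set_size)]
    query <- universe[sample(N, query_size)]
    k <- length(intersect(query, set_genes))
    res <- geneset_overlap(query, list(s = set_genes), universe_size = N)
    expect_equal(res$p, oracle_hyper(N, set_size, query_size, k), tolerance = 1e-10)
  }
})

test_that("hypergeometric degenerate cases and validation", {
  res <- geneset_overlap(paste0("g", 1:3), list(s = paste0("h", 1:4)),
                         universe_size = 20)
  expect_equal(res$p, 1)                         # disjoint: P(X >= 0) = 1
  whole <- geneset_overlap(paste0("g", 1:3),
                           list(s = paste0("g", 1:10)), universe_size = 10)
  expect_equal(whole$p, 1)                       # set = universe forces overlap
  expect_error(geneset_overlap(paste0("g", 1:3), list(s = paste0("g", 1:10)),
                               universe_size = 5), "larger than")
  multi <- geneset_overlap(paste0("g", 1:4),
                           list(a = paste0("g", 1:5), b = paste0("h", 1:5)),
                           universe_size = 20)
  expect_equal(multi$q, p.adjust(multi$p, "BH"))
})

test_that("group report restricts to the requested genes consistently", {
  ds <- simulate_expression(sim_config(n_patients = 2, cells_per_patient = c(20, 20),
                                       n_genes = 200, n_housekeeping = 20,
                                       n_progression_genes = 30, n_groups = 2,
                                       group_mixture = rbind(c(1, 0), c(0, 1)),
                                       seed = 77))
  expr <- tpm_from_counts(ds)
  g <- setNames(paste0("L", ds$true_group), ds$cell_ids)
  genes <- ds$true_progression_genes[1:5]
  expect_warning(rep1 <- geneset_group_report(expr, g, c(genes, "NOPE")), "unknown")
  expect_setequal(rep1$gene_id, genes)
  pw <- pairwise_fc(expr, g, list(c("L1", "L2")))
  expect_equal(rep1$log2fc_L1_vs_L2,
               pw$log2_fc[match(genes, pw$gene_id)], tolerance = 1e-12)
  expect_equal(nrow(geneset_group_report(expr, g, character(0))), 0)
})
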