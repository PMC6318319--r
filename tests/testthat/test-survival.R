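toy_records <- function(time, event, ids = sprintf("s%02d", seq_along(time))) {
  data.frame(sample_id = ids, time_days = time, event = event,
             stringsAsFactors = FALSE)
}

test_that("probe collapsing averages multi-probe genes", {
  m <- cbind(p1 = c(4, 1), p2 = c(6, 3), p3 = c(10, 20), px = c(0, 0))
  rownames(m) <- c("s1", "s2")
  map <- data.frame(probe_id = c("p1", "p2", "p3"),
                    gene_id = c("GA", "GA", "GB"))
  expect_warning(out <- collapse_probes(m, map), "unmapped")
  expect_equal(out[, "GA"], c(s1 = 5, s2 = 2))      # mean of 4 and 6
  expect_equal(out[, "GB"], c(s1 = 10, s2 = 20))    # single probe unchanged
  # random map vs from-scratch group-by mean
  set.seed(4)
  m2 <- matrix(rnorm(60), 5, 12, dimnames = list(paste0("s", 1:5), paste0("p", 1:12)))
  map2 <- data.frame(probe_id = paste0("p", 1:12),
                     gene_id = sample(paste0("G", 1:4), 12, replace = TRUE))
  out2 <- collapse_probes(m2, map2)
  for (g in unique(map2$gene_id)) {
    manual <- rowMeans(m2[, map2$probe_id[map2$gene_id == g], drop = FALSE])
    expect_equal(out2[, g], manual, tolerance = 1e-12)
  }
  expect_error(collapse_probes(m, data.frame(probe_id = c("p1", "p1"),
                                             gene_id = c("GA", "GB"))),
               "more than one")
})

test_that("standardization gives exact zero mean and unit sd", {
  m <- cbind(g1 = c(1, 3, 5), g2 = c(2, 2, 2))
  rownames(m) <- paste0("s", 1:3)
  expect_warning(z <- standardize(m), "zero-variance")
  expect_equal(unname(z[, "g1"]), c(-1, 0, 1))
  expect_equal(unname(z[, "g2"]), c(0, 0, 0))
  set.seed(8)
  m2 <- matrix(rnorm(40, 5, 3), 10, 4, dimnames = list(paste0("s", 1:10), paste0("g", 1:4)))
  z2 <- standardize(m2)
  expect_equal(unname(colMeans(z2)), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(apply(z2, 2, sd)), rep(1, 4), tolerance = 1e-10)
  expect_equal(standardize(z2), z2, tolerance = 1e-10)  # idempotent
  expect_error(standardize(m2[1, , drop = FALSE]), "2 samples")
})

test_that("k-means dichotomization finds the optimal split and labels by score", {
  # well-separated 1-D blobs: any seed gives a perfect split
  x <- matrix(c(rnorm(10, -5, 0.2), rnorm(10, 5, 0.2)), ncol = 1,
              dimnames = list(sprintf("s%02d", 1:20), "g"))
  for (seed in 1:3) {
    rg <- kmeans_dichotomize(x, seed = seed)
    expect_identical(unname(rg$label_of_sample), rep(c("low", "high"), each = 10))
  }
  # 6-point toy: compare with exhaustive minimization of within-cluster SS
  set.seed(12)
  y <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("s", 1:6), c("a", "b")))
  wss <- function(assign) {
    sum(vapply(unique(assign), function(k) {
      pts <- y[assign == k, , drop = FALSE]
      sum(sweep(pts, 2, colMeans(pts))^2)
    }, numeric(1)))
  }
  best <- NULL; best_w <- Inf
  for (code in 1:(2^5 - 1)) {                 # all non-trivial 2-partitions
    assign <- c(0, as.integer(intToBits(code)[1:5]))
    if (length(unique(assign)) < 2) next
    w <- wss(assign)
    if (w < best_w) { best_w <- w; best <- assign }
  }
  rg <- kmeans_dichotomize(y, n_restarts = 50, seed = 1)
  expect_equal(adjusted_rand_index(rg$label_of_sample, best), 1)
  # duplicating every sample keeps the same partition
  y2 <- rbind(y, y)
  rownames(y2) <- paste0("s", 1:12)
  rg2 <- kmeans_dichotomize(y2, n_restarts = 50, seed = 1)
  expect_identical(unname(rg2$label_of_sample[1:6]),
                   unname(rg2$label_of_sample[7:12]))
  expect_error(kmeans_dichotomize(y, k = 7), "exceeds")
})

test_that("KM product-limit matches the hand toy and survfit", {
  # times (1, 2+, 3): S = 2/3 after t=1, 0 after t=3
  rec <- toy_records(c(1, 2, 3), c(1, 0, 1))
  km <- km_estimate(rec)$all
  expect_equal(km$survival, c(2 / 3, 2 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))
  # no events: flat at 1
  flat <- km_estimate(toy_records(c(2, 5, 9), c(0, 0, 0)))$all
  expect_true(all(flat$survival == 1))
  # no censoring: complement of the ecdf
  t2 <- c(4, 1, 3, 2, 5)
  km2 <- km_estimate(toy_records(t2, rep(1, 5)))$all
  expect_equal(km2$survival, 1 - ecdf(t2)(km2$time))
  # agreement with survival::survfit on random censored data
  set.seed(5)
  rec3 <- toy_records(rexp(40, 0.1), rbinom(40, 1, 0.7))
  km3 <- km_estimate(rec3)$all
  fit <- survival::survfit(survival::Surv(time_days, event) ~ 1, data = rec3)
  expect_equal(km3$survival[km3$n_event > 0],
               fit$surv[fit$n.event > 0], tolerance = 1e-12)
  expect_error(km_estimate(toy_records(-1, 1)), "negative")
})

test_that("log-rank matches the O/E/V oracle and its invariances", {
  set.seed(6)
  rec <- toy_records(round(rexp(30, 0.05)) + 1, rbinom(30, 1, 0.8))
  grp <- setNames(rep(c("high", "low"), 15), rec$sample_id)
  res <- logrank_test(rec, grp)
  o <- oracle_logrank(rec$time_days, rec$event, unname(grp))
  expect_equal(res$chi_square, o$chi_square, tolerance = 1e-10)
  expect_equal(res$p, o$p, tolerance = 1e-10)
  # relabeling invariance
  flipped <- setNames(ifelse(grp == "high", "low", "high"), names(grp))
  expect_equal(logrank_test(rec, flipped)$chi_square, res$chi_square)
  # time-unit rescaling invariance
  rec2 <- rec; rec2$time_days <- rec2$time_days * 365.25
  expect_equal(logrank_test(rec2, grp)$p, res$p, tolerance = 1e-12)
  # identical groups: two copies of the same records -> chi-square 0
  twin <- rbind(rec, rec)
  twin$sample_id <- sprintf("t%02d", seq_len(nrow(twin)))
  tg <- setNames(rep(c("a", "b"), each = nrow(rec)), twin$sample_id)
  twin_res <- logrank_test(twin, tg)
  expect_lt(twin_res$chi_square, 1e-10)
  expect_equal(twin_res$p, 1, tolerance = 1e-6)
  expect_error(logrank_test(rec, setNames(rep("a", 30), rec$sample_id)),
               "2 groups")
})

test_that("hazard ratio behaves under symmetry and degenerate input", {
  set.seed(7)
  rec <- toy_records(rexp(60, 0.02), rbinom(60, 1, 0.8))
  grp <- setNames(rep(c("high", "low"), 30), rec$sample_id)
  hr <- hazard_ratio(rec, grp)
  expect_true(hr$ci_low <= hr$hr && hr$hr <= hr$ci_high)
  flipped <- setNames(ifelse(grp == "high", "low", "high"), names(grp))
  hr_flip <- hazard_ratio(rec, flipped)
  expect_equal(hr_flip$hr, 1 / hr$hr, tolerance = 1e-6)
  # two copies of the same records: HR = 1
  twin <- rbind(rec, rec)
  twin$sample_id <- sprintf("t%03d", seq_len(nrow(twin)))
  tg <- setNames(rep(c("high", "low"), each = nrow(rec)), twin$sample_id)
  expect_equal(hazard_ratio(twin, tg)$hr, 1, tolerance = 1e-8)
  # no events in one group -> monotone likelihood error
  rec0 <- rec
  rec0$event[grp == "high"] <- 0
  expect_error(hazard_ratio(rec0, grp), "monotone")
})

test_that("stratification wrapper recovers a planted hazard difference", {
  sv <- simulate_survival_cohort(survival_sim_config(n_samples = 200, true_hr = 3,
                                                     seed = 15))
  strat <- stratify_survival(sv$expression, sv$survival,
                             colnames(sv$expression), seed = 1)
  expect_gt(strat$cox$hr, 1)
  expect_lt(strat$logrank$p, 0.01)
  # planted high-risk half should align with the recovered labels
  agreement <- mean((strat$risk_groups$label_of_sample == "high") ==
                    sv$true_high[names(strat$risk_groups$label_of_sample)])
  expect_gt(agreement, 0.9)
  # arm filtering restricts the records
  strat_b <- stratify_survival(sv$expression, sv$survival,
                               colnames(sv$expression),
                               arm = "bortezomib", seed = 1)
  expect_equal(strat_b$n_samples, sum(sv$survival$arm == "bortezomib"))
})
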