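test_that("TE is the polysomal/total intensity ratio, per project and pooled", {
  toy <- toy_summarized(te_wt = c(1, 2, 0.5), te_mut = c(1, 1, 1))
  te <- compute_te(toy$matrix, toy$sheet)
  expect_equal(te$te_wt_I, c(1, 2, 0.5))
  expect_equal(te$mean_te_wt, c(1, 2, 0.5))
  expect_equal(te$mean_te_mut, c(1, 1, 1))
  expect_equal(te$mean_ratio, c(1, 0.5, 2))
  # HP == T everywhere gives TE 1
  same <- toy_summarized(te_wt = rep(1, 4), te_mut = rep(1, 4))
  expect_true(all(compute_te(same$matrix, same$sheet)$mean_te_wt == 1))
})

test_that("compute_te validates design and intensities", {
  toy <- toy_summarized(te_wt = c(1, 2), te_mut = c(1, 1))
  m <- toy$matrix[, toy$sheet$fraction == "T"]
  attr(m, "scale") <- "linear"
  expect_error(compute_te(m, toy$sheet[toy$sheet$fraction == "T", ]),
               "design error")
  bad <- toy$matrix; bad[1, 1] <- 0
  expect_error(compute_te(bad, toy$sheet), "non-positive")
  expect_error(compute_te(toy$matrix, toy$sheet, numerator = "LP"),
               "design error")
})

test_that("pooled TE modes differ as ratio-of-means vs mean-of-ratios", {
  toy <- toy_summarized(te_wt = c(2, 2), te_mut = c(1, 1),
                        abundance = c(10, 1000))
  toy$matrix[1, "WT_HP_II"] <- 40  # perturb one project
  a <- compute_te(toy$matrix, toy$sheet, pooled = "ratio_of_means")
  b <- compute_te(toy$matrix, toy$sheet, pooled = "mean_of_ratios")
  expect_equal(a$mean_te_wt[1], mean(c(20, 40, 20)) / 10)
  expect_equal(b$mean_te_wt[1], mean(c(2, 4, 2)))
})

test_that("pooled t-test matches the textbook example and stats::t.test", {
  r <- gene_ttest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(abs(r$statistic)), 3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)
  expect_equal(unname(r$p_value), 0.0214, tolerance = 1e-2)
  set.seed(9)
  for (i in 1:100) {
    a <- rnorm(3); b <- rnorm(3, sample(c(0, 2), 1))
    ref <- t.test(a, b, var.equal = TRUE)
    r <- gene_ttest(a, b)
    expect_equal(unname(r$p_value), ref$p.value, tolerance = 1e-10)
    expect_equal(unname(r$statistic), unname(ref$statistic), tolerance = 1e-10)
  }
})

test_that("degenerate zero-variance t-tests are totalized and flagged", {
  same <- gene_ttest(c(2, 2, 2), c(2, 2, 2))
  expect_equal(unname(same$p_value), 1)
  expect_true(same$degenerate)
  diff <- gene_ttest(c(2, 2, 2), c(3, 3, 3))
  expect_equal(unname(diff$p_value), 0)
  expect_true(diff$degenerate)
  ident <- gene_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(ident$p_value), 1)
  expect_false(ident$degenerate)
  expect_error(gene_ttest(1, c(1, 2)), "statistics error")
})

test_that("classification applies the ratio and p-value rule", {
  te <- data.frame(gene_id = c("down", "flat", "up", "nsig"),
                   mean_ratio = c(0.6, 1, 1.5, 0.5),
                   p_value = c(0.03, 0.03, 0.05, 0.5))
  cl <- classify_genes(te)
  expect_identical(cl$down_set, "down")
  expect_identical(cl$up_set, "up")
  expect_error(classify_genes(te, down = 1.5, up = 1.4), "configuration error")
  none <- classify_genes(data.frame(gene_id = "g", mean_ratio = 1, p_value = 0))
  expect_length(none$down_set, 0)
  expect_length(none$up_set, 0)
})

test_that("classification is monotone in alpha and thresholds, order-invariant", {
  set.seed(21)
  for (i in 1:100) {
    te <- data.frame(gene_id = sprintf("g%03d", 1:60),
                     mean_ratio = 2^rnorm(60, 0, 0.5),
                     p_value = runif(60))
    loose <- classify_genes(te, down = 0.71, up = 1.4, alpha = 0.1)
    tight <- classify_genes(te, down = 0.6, up = 1.6, alpha = 0.05)
    expect_true(all(tight$down_set %in% loose$down_set))
    expect_true(all(tight$up_set %in% loose$up_set))
    expect_length(intersect(loose$down_set, loose$up_set), 0)
    shuf <- classify_genes(te[sample(60), ], 0.71, 1.4, 0.1)
    expect_setequal(shuf$down_set, loose$down_set)
    expect_setequal(shuf$up_set, loose$up_set)
  }
})

test_that("threshold counts use inclusive comparisons and nest", {
  m <- tabulate_thresholds(c(2.1, 1.5, 1.0, 0.6, 0.4))
  expect_equal(unname(m[1, ]), c(2, 1, 2, 1))
  expect_equal(unname(tabulate_thresholds(rep(1, 5))[1, ]), c(0, 0, 0, 0))
  set.seed(4)
  for (i in 1:100) {
    v <- 2^rnorm(50, 0, 0.7)
    m <- tabulate_thresholds(v)
    expect_lte(m[1, 2], m[1, 1])  # TE >= 2 within TE >= 1.5
    expect_lte(m[1, 4], m[1, 3])  # TE <= 0.5 within TE <= 0.67
  }
})

test_that("dependency fractions use strict inequalities per stratum", {
  te <- data.frame(gene_id = c("a", "b"), mean_te_wt = c(2, 2),
                   mean_te_mut = c(1, 3))
  d <- suppressWarnings(dependency_fractions(te))  # low-TE stratum is empty
  expect_equal(d$high_frac, 0.5)
  expect_equal(d$n_high, 2)
  eq <- data.frame(gene_id = c("a", "b"), mean_te_wt = c(2, 0.5),
                   mean_te_mut = c(2, 0.5))
  deq <- dependency_fractions(eq)
  expect_equal(deq$high_frac, 0)
  expect_equal(deq$low_frac_wt_gt, 0)
  expect_equal(deq$low_frac_wt_lt, 0)
  empty <- data.frame(gene_id = "a", mean_te_wt = 1, mean_te_mut = 1)
  expect_warning(de <- dependency_fractions(empty), "empty gene set")
  expect_true(is.na(de$high_frac))
})

test_that("MA statistics follow the log-ratio/log-average definitions", {
  s <- ma_stats(c(8, 8), c(2, 2))
  expect_equal(s$M, c(2, 2))
  expect_equal(s$A, c(2, 2))
  expect_equal(s$variance_M, 0)
  s2 <- ma_stats(c(2, 4), c(4, 2))
  expect_equal(s2$M, c(-1, 1))
  expect_equal(s2$variance_M, 2)  # sample variance, n - 1
  same <- ma_stats(c(3, 7, 11), c(3, 7, 11))
  expect_true(all(same$M == 0) && same$variance_M == 0)
  expect_error(ma_stats(c(1, -1), c(1, 1)), "non-positive")
  expect_error(ma_stats(1, 1), "statistics error")
})

test_that("TE regression recovers hand-computed OLS slopes", {
  te <- data.frame(gene_id = c("a", "b", "c"),
                   mean_te_wt = 2^c(-1.3, 0, 1.3),
                   mean_te_mut = 2^c(-1, 0, 1))
  r <- te_regression(te)
  expect_equal(r$slope, 1.3)
  expect_equal(r$intercept, 0)
  ident <- data.frame(gene_id = c("a", "b"), mean_te_wt = c(0.5, 2),
                      mean_te_mut = c(0.5, 2))
  ri <- te_regression(ident)
  expect_equal(ri$slope, 1)
  expect_equal(ri$intercept, 0)
  # orientation swap inverts the role of the strains
  rs <- te_regression(te, response = "mut")
  expect_equal(rs$slope, 1 / 1.3)
  expect_error(te_regression(te[1, ]), "statistics error")
})

test_that("OLS slope matches the closed-form covariance formula", {
  set.seed(11)
  x <- rnorm(50); y <- 1.3 * x + rnorm(50, 0, 0.2)
  te <- data.frame(gene_id = sprintf("g%d", 1:50),
                   mean_te_wt = 2^y, mean_te_mut = 2^x)
  r <- te_regression(te)
  expect_equal(r$slope, cov(x, y) / var(x), tolerance = 1e-12)
  expect_equal(r$intercept, mean(y) - r$slope * mean(x), tolerance = 1e-12)
})

test_that("stratum mean WT/mutant ratios average projects then genes", {
  toy <- toy_summarized(te_wt = c(3, 3, 0.2, 0.2),
                        te_mut = c(3 / 1.2, 3 / 1.4, 0.2, 0.2))
  te <- compute_te(toy$matrix, toy$sheet)
  above <- group_mean_ratio(te, "above")
  expect_equal(above$mean_ratio, mean(c(1.2, 1.4)))
  expect_equal(above$n_genes, 2)
  below <- group_mean_ratio(te, "below")
  expect_equal(below$mean_ratio, 1)
  flat <- toy_summarized(te_wt = c(1, 1), te_mut = c(1, 1))
  expect_error(group_mean_ratio(compute_te(flat$matrix, flat$sheet), "above"),
               "empty selection")
})
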