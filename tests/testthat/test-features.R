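toy_features <- function() {
  data.frame(
    gene_id = letters[1:6],
    utr5_len = c(100L, 200L, 50L, 80L, 300L, 60L),
    orf_len = c(300L, 1200L, 600L, 2400L, 900L, 450L),
    n_uorfs = c(0L, 1L, 2L, 0L, 0L, 1L),
    essential = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
    category = c("A", "A", "A", "B", "B", "B"),
    ribosome_density = c(0.2, 0.7, 0.25, 0.4, 0.8, 0.6),
    peak_ribosomes = c(1L, 8L, 2L, 3L, 7L, 3L),
    stringsAsFactors = FALSE
  )
}

test_that("group feature statistics give mean, SEM, and a reference test", {
  f <- toy_features()
  g <- group_feature_stats(c("a", "b"), f, "utr5_len")
  expect_equal(g$mean, 150)
  expect_equal(g$sem, 50)
  expect_equal(g$n, 2)
  # set == reference: no difference by construction
  all_g <- group_feature_stats(f$gene_id, f, "utr5_len")
  expect_equal(all_g$p_value, 1)
  expect_equal(all_g$mean, all_g$reference_mean)
  expect_error(group_feature_stats("a", f, "utr5_len"), "statistics error")
  expect_error(group_feature_stats(c("a", "b"), f, "nope"), "data error")
})

test_that("feature tests dispatch to the chosen two-sample procedure", {
  f <- toy_features()
  set <- c("a", "b", "e")
  w <- group_feature_stats(set, f, "utr5_len", reference = c("c", "d", "f"))
  s <- group_feature_stats(set, f, "utr5_len", reference = c("c", "d", "f"),
                           test = "student")
  m <- group_feature_stats(set, f, "utr5_len", reference = c("c", "d", "f"),
                           test = "mann-whitney")
  v1 <- c(100, 200, 300); v2 <- c(50, 80, 60)
  expect_equal(w$p_value, t.test(v1, v2)$p.value)
  expect_equal(s$p_value, t.test(v1, v2, var.equal = TRUE)$p.value)
  expect_equal(m$p_value, wilcox.test(v1, v2, exact = FALSE)$p.value)
})

test_that("uORF statistics summarize counts per transcript", {
  f <- toy_features()
  u <- uorf_stats(c("a", "b", "c"), f)
  expect_equal(u$mean, 1)
  expect_equal(u$sem, 0.5774, tolerance = 1e-4)
  z <- uorf_stats(c("a", "d", "e"), f)
  expect_equal(z$mean, 0)
})

# Exhaustive hypergeometric two-sided p for a 2x2 table with fixed margins:
# sum over all tables with probability <= the observed one (with the small
# relative slack R's fisher.test uses).
enum_fisher_p <- function(k, n, K, N) {
  support <- max(0, n + K - N):min(n, K)
  prob <- function(x) choose(K, x) * choose(N - K, n - x) / choose(N, n)
  p_obs <- prob(k)
  sum(vapply(support, prob, 1)[vapply(support, prob, 1) <= p_obs * (1 + 1e-7)])
}

test_that("Fisher p-values match exhaustive hypergeometric enumeration", {
  set.seed(12)
  for (i in 1:40) {
    N <- sample(8:60, 1); K <- sample(2:(N - 2), 1); n <- sample(2:(N - 2), 1)
    k <- sample(max(0, n + K - N):min(n, K), 1)
    tab <- matrix(c(k, n - k, K - k, N - n - (K - k)), 2)
    expect_equal(fisher.test(tab)$p.value, enum_fisher_p(k, n, K, N),
                 tolerance = 1e-12)
  }
})

test_that("category enrichment computes counts, fold change, and direction", {
  f <- toy_features()
  e <- category_enrichment(c("a", "b"), f)
  ea <- e[e$category == "A", ]
  expect_equal(ea$set_count, 2)
  expect_equal(ea$universe_count, 3)
  expect_equal(ea$log2_fold_enrichment, log2((2 / 2) / (3 / 6)))
  # hand enumeration over the 15 possible 2-gene sets: P(X=0)=P(X=2)=0.2,
  # P(X=1)=0.6, so the two-sided p for observing 2 of 3 category genes is 0.4
  expect_equal(ea$fisher_p, 0.4, tolerance = 1e-12)
  expect_equal(e$bonferroni_p, pmin(1, e$fisher_p * nrow(e)))
  eb <- e[e$category == "B", ]
  expect_identical(eb$direction, "underrepresented")
  expect_lt(eb$log2_fold_enrichment, 0)
  # set == universe: every category at fold 1, p 1
  all_e <- category_enrichment(f$gene_id, f)
  expect_true(all(all_e$log2_fold_enrichment == 0))
  expect_true(all(all_e$fisher_p == 1))
  expect_error(category_enrichment(c("zz"), f), "subset of the universe")
})

test_that("one-sided enrichment tail matches exhaustive set enumeration", {
  # universe of 6 with category {a,b,c}: enumerate all 2-gene sets and count
  # those with >= 2 category members; the observed set {a,b} sits in a tail
  # of probability 3/15 = 0.2
  sets <- combn(letters[1:6], 2)
  tail_count <- sum(colSums(matrix(sets %in% c("a", "b", "c"), 2)) >= 2)
  expect_equal(tail_count / ncol(sets), 0.2)
})

test_that("essential-gene frequency is tested against the universe", {
  f <- toy_features()
  e <- essential_fraction(c("b", "d", "e", "f"), f)
  expect_equal(e$fraction, 0)
  expect_equal(e$universe_fraction, 2 / 6)
  sym <- rbind(toy_features(), within(toy_features(), gene_id <- paste0(gene_id, "2")))
  # balanced 2x2 gives p = 1 by symmetry
  ebal <- essential_fraction(c("a", "b", "c", "d", "e", "f"), sym)
  expect_equal(ebal$fisher_p, 1)
  f$essential <- NA
  expect_error(essential_fraction("a", f), "data error")
})

test_that("random same-size gene sets give roughly uniform feature p-values", {
  cfg <- sim_config(n_genes = 400L, seed = 5)
  f <- simulate_features(cfg)
  set.seed(6)
  p <- replicate(200, {
    s <- sample(f$gene_id, 40)
    group_feature_stats(s, f, "utr5_len", reference = setdiff(f$gene_id, s))$p_value
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.05)
})

test_that("candidate reports resolve aliases and tolerate missing ids", {
  toy <- toy_summarized(te_wt = c(1, 1, 2), te_mut = c(1, 1.2, 1))
  te <- compute_te(toy$matrix, toy$sheet)
  syn <- data.frame(alias = "GENE2", gene_id = "g02", stringsAsFactors = FALSE)
  rep <- candidate_gene_report(c("g01", "GENE2", "missing"), te, synonyms = syn)
  expect_equal(rep$mean_ratio[1], 1)
  expect_equal(rep$ratio_sem[1], 0)
  expect_equal(rep$mean_ratio[2], 1.2)
  expect_false(rep$found[3])
  # SEM of per-project ratios: (1.0, 1.2, 1.4) -> 1.2 +- 0.115
  toy2 <- toy_summarized(te_wt = c(1, 1), te_mut = c(1, 1))
  toy2$matrix[1, c("mutant_HP_I", "mutant_HP_II", "mutant_HP_III")] <-
    100 * c(1.0, 1.2, 1.4)
  te2 <- compute_te(toy2$matrix, toy2$sheet)
  r2 <- candidate_gene_report("g01", te2)
  expect_equal(r2$mean_ratio, 1.2)
  expect_equal(r2$ratio_sem, 0.11547, tolerance = 1e-4)
})

test_that("density cross-referencing filters and summarizes TE groups", {
  f <- toy_features()
  toy <- toy_summarized(te_wt = c(2, 1, 1.8, 0.8, 1, 1.2),
                        te_mut = c(1.6, 1, 1.5, 0.9, 1, 1.1))
  te <- compute_te(toy$matrix, toy$sheet)
  te$gene_id <- f$gene_id
  d <- density_crossref(te, f, density_max = 0.25)
  expect_equal(d$n, 2)  # genes a and c: peak 1-3 and density <= 0.25
  expect_setequal(d$gene_ids, c("a", "c"))
  expect_equal(d$mean_te_wt, mean(c(2, 1.8)))
  o <- density_crossref(te, f, orf_max = 625)
  expect_setequal(o$gene_ids, c("a", "c", "f"))
  expect_error(density_crossref(te, f, density_max = 1e-6), "retained no genes")
  expect_error(density_crossref(te, f), "configuration error")
})
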