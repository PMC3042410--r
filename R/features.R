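#' Group statistics for a structural gene feature
#'
#' Mean and standard error of one feature (e.g. 5'UTR length) over a gene
#' set, with a two-tailed test against a reference set (all annotated genes
#' by default, or a second gene set). Genes missing the feature are dropped
#' pairwise.
#'
#' @param gene_set Character vector of gene ids.
#' @param features Feature table (`gene_id` plus annotation columns).
#' @param field Feature column name.
#' @param reference Reference gene ids (default: all genes in `features`).
#'   Genes of `gene_set` are not excluded from the reference.
#' @param test `"welch"` (default), `"student"`, or `"mann-whitney"`.
#' @return A list: `mean`, `sem`, `n`, `reference_mean`, `p_value`, `test`.
#' @export
group_feature_stats <- function(gene_set, features, field,
                                reference = features$gene_id,
                                test = c("welch", "student", "mann-whitney")) {
  test <- match.arg(test)
  if (!field %in% names(features))
    stop("data error: no feature column '", field, "'", call. = FALSE)
  v <- features[[field]][match(gene_set, features$gene_id)]
  v <- v[!is.na(v)]
  r <- features[[field]][match(reference, features$gene_id)]
  r <- r[!is.na(r)]
  if (length(v) < 2L || length(r) < 2L)
    stop("statistics error: fewer than two usable genes", call. = FALSE)
  p <- if (setequal(gene_set, reference)) 1 else switch(
    test,
    welch = stats::t.test(v, r)$p.value,
    student = stats::t.test(v, r, var.equal = TRUE)$p.value,
    `mann-whitney` = stats::wilcox.test(v, r, exact = FALSE)$p.value
  )
  list(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)), n = length(v),
       reference_mean = mean(r), p_value = p, test = test)
}

#' Upstream ORF burden of a gene set
#'
#' Mean number of uORFs per transcript with its SEM, via
#' [group_feature_stats()] on the `n_uorfs` column.
#'
#' @inheritParams group_feature_stats
#' @return As [group_feature_stats()].
#' @export
uorf_stats <- function(gene_set, features, reference = features$gene_id,
                       test = c("welch", "student", "mann-whitney")) {
  group_feature_stats(gene_set, features, "n_uorfs", reference = reference,
                      test = match.arg(test))
}

#' Functional-category enrichment of a gene set
#'
#' Per category, a two-sided Fisher's exact test on the 2x2 table of
#' set/non-set by category/non-category membership over the universe, with
#' Bonferroni correction over the tested categories and the log2 fold
#' enrichment `log2((set_count/set_size) / (universe_count/universe_size))`.
#' Categories with fewer than two members in the universe are skipped.
#'
#' @param gene_set Character vector of gene ids, a subset of `universe`.
#' @param features Feature table with a `category` column (a single label
#'   per gene, or a list column / `;`-separated labels for multi-membership).
#' @param universe Gene ids defining the tested universe (default: all genes
#'   in `features`).
#' @return A `data.frame`: `category`, `set_count`, `universe_count`,
#'   `log2_fold_enrichment`, `fisher_p`, `bonferroni_p`, `direction`.
#' @export
category_enrichment <- function(gene_set, features, universe = features$gene_id) {
  if (!all(gene_set %in% universe))
    stop("data error: gene_set must be a subset of the universe", call. = FALSE)
  cats <- features$category[match(universe, features$gene_id)]
  if (is.character(cats) && any(grepl(";", cats, fixed = TRUE)))
    cats <- strsplit(cats, ";", fixed = TRUE)
  membership <- if (is.list(cats)) cats else as.list(cats)
  all_cats <- sort(unique(unlist(membership)))
  in_set <- universe %in% gene_set
  N <- length(universe); n <- sum(in_set)

  rows <- lapply(all_cats, function(cc) {
    in_cat <- vapply(membership, function(m) cc %in% m, logical(1))
    K <- sum(in_cat)
    if (K < 2L) return(NULL)  # untestable category
    k <- sum(in_cat & in_set)
    tab <- matrix(c(k, n - k, K - k, N - n - (K - k)), 2L)
    p <- stats::fisher.test(tab)$p.value
    lfe <- log2((k / n) / (K / N))
    data.frame(category = cc, set_count = k, universe_count = K,
               log2_fold_enrichment = lfe, fisher_p = p,
               direction = if (k / n >= K / N) "enriched" else "underrepresented",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("data error: no testable categories in the universe", call. = FALSE)
  out$bonferroni_p <- pmin(1, out$fisher_p * nrow(out))
  out <- out[, c("category", "set_count", "universe_count",
                 "log2_fold_enrichment", "fisher_p", "bonferroni_p", "direction")]
  rownames(out) <- NULL
  out
}

#' Essential-gene frequency of a gene set
#'
#' Fraction of essential genes in the set and a Fisher exact test of that
#' frequency against the universe.
#'
#' @param gene_set Character vector of gene ids.
#' @param features Feature table with a logical `essential` column.
#' @param universe Universe gene ids (default: all annotated genes).
#' @return A list: `fraction`, `n`, `universe_fraction`, `fisher_p`.
#' @export
essential_fraction <- function(gene_set, features, universe = features$gene_id) {
  ess <- features$essential[match(universe, features$gene_id)]
  if (all(is.na(ess)))
    stop("data error: no essentiality flags", call. = FALSE)
  in_set <- universe %in% gene_set
  k <- sum(ess & in_set, na.rm = TRUE); n <- sum(in_set & !is.na(ess))
  K <- sum(ess, na.rm = TRUE); N <- sum(!is.na(ess))
  tab <- matrix(c(k, n - k, K - k, (N - n) - (K - k)), 2L)
  list(fraction = k / n, n = n, universe_fraction = K / N,
       fisher_p = stats::fisher.test(tab)$p.value)
}

#' Report TE ratios for named candidate genes
#'
#' For each requested gene, the mean mutant/WT TE ratio over projects, its
#' SEM, and the per-gene t-test p-value, looked up from a `te_table`.
#' Aliases are resolved through an optional synonym column; unresolvable ids
#' are listed as missing rather than raising an error.
#'
#' @param gene_ids Character vector of gene ids (or aliases).
#' @param te A `te_table` from [compute_te()].
#' @param synonyms Optional data.frame with columns `alias`, `gene_id`.
#' @return A `data.frame`: `gene_id`, `mean_ratio`, `ratio_sem`, `p_value`,
#'   `found`.
#' @export
candidate_gene_report <- function(gene_ids, te, synonyms = NULL) {
  resolved <- gene_ids
  if (!is.null(synonyms)) {
    hit <- match(gene_ids, synonyms$alias)
    resolved[!is.na(hit)] <- synonyms$gene_id[hit[!is.na(hit)]]
  }
  i <- match(resolved, te$gene_id)
  data.frame(gene_id = gene_ids,
             mean_ratio = te$mean_ratio[i],
             ratio_sem = te$ratio_sem[i],
             p_value = te$p_value[i],
             found = !is.na(i),
             stringsAsFactors = FALSE)
}

#' Cross-reference TE with ribosome-density annotations
#'
#' Reproduces the light-polysome cross-referencing of low-occupancy mRNAs:
#' filters genes to those whose peak ribosome occupancy lies in
#' `peak_ribosome_range` and that satisfy either a ribosome-density ceiling
#' (`density_max`, ribosomes per 100 nt) or an ORF-length ceiling
#' (`orf_max`, nt), then summarizes the group's mean TE (+- SEM) per strain.
#'
#' @param te A `te_table` (typically LP-based).
#' @param features Feature table with `ribosome_density`, `peak_ribosomes`,
#'   `orf_len`.
#' @param density_max Optional maximum ribosome density (inclusive).
#' @param orf_max Optional exclusive ORF-length ceiling.
#' @param peak_ribosome_range Inclusive range of peak ribosomes (default
#'   1-3).
#' @return A list: `n`, `gene_ids`, `mean_te_wt`, `sem_te_wt`,
#'   `mean_te_mut`, `sem_te_mut`.
#' @export
density_crossref <- function(te, features, density_max = NULL, orf_max = NULL,
                             peak_ribosome_range = c(1L, 3L)) {
  if (is.null(density_max) && is.null(orf_max))
    stop("configuration error: give density_max or orf_max", call. = FALSE)
  f <- features[match(te$gene_id, features$gene_id), ]
  keep <- !is.na(f$peak_ribosomes) &
    f$peak_ribosomes >= peak_ribosome_range[1L] &
    f$peak_ribosomes <= peak_ribosome_range[2L]
  if (!is.null(density_max)) keep <- keep & !is.na(f$ribosome_density) &
      f$ribosome_density <= density_max
  if (!is.null(orf_max)) keep <- keep & !is.na(f$orf_len) & f$orf_len < orf_max
  if (!any(keep))
    stop("statistics error: filter retained no genes", call. = FALSE)
  sub <- te[keep, ]
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  list(n = nrow(sub), gene_ids = sub$gene_id,
       mean_te_wt = mean(sub$mean_te_wt), sem_te_wt = sem(sub$mean_te_wt),
       mean_te_mut = mean(sub$mean_te_mut), sem_te_mut = sem(sub$mean_te_mut))
}
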