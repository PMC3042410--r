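#' Compute per-gene translational efficiencies
#'
#' The translational efficiency (TE) of a gene is the ratio of its intensity
#' in a polysomal fraction to its intensity in total RNA (HP/T, or LP/T),
#' computed per strain and project from technical-replicate-averaged
#' summaries. Two averaging modes are populated:
#'
#' * mode A ("pooled"): the mean TE per strain computed from all arrays
#'   pooled across projects, as the ratio of mean polysomal intensity to
#'   mean total intensity (`pooled = "ratio_of_means"`, the default) or as
#'   the mean of per-project TEs (`"mean_of_ratios"`);
#' * mode B ("per-project"): per-project mutant/wild-type TE ratios,
#'   averaged over projects, with their SEM and a two-tailed pooled-variance
#'   Student's t-test of the three mutant versus three wild-type per-project
#'   TE values.
#'
#' @param x Summarized gene x group matrix from [summarize_tech_reps()]
#'   (linear or log2-flagged; log2 input is converted to linear).
#' @param sheet The group-level sheet returned with `x` (columns `array_id`,
#'   `strain`, `fraction`, `project`).
#' @param numerator Polysomal fraction for the TE numerator: `"HP"` or
#'   `"LP"`.
#' @param pooled Mode-A estimator, see above.
#' @return A `data.frame` of class `"te_table"`: `gene_id`; per-project TEs
#'   `te_wt_<proj>` and `te_mut_<proj>`; pooled `mean_te_wt`, `mean_te_mut`;
#'   per-project ratios `ratio_<proj>` (mutant/WT); `mean_ratio`,
#'   `ratio_sem`; `p_value`, `p_adj` (Benjamini-Hochberg, informational) and
#'   `degenerate` (zero-variance t-test flag).
#' @export
compute_te <- function(x, sheet, numerator = c("HP", "LP"),
                       pooled = c("ratio_of_means", "mean_of_ratios")) {
  numerator <- match.arg(numerator)
  pooled <- match.arg(pooled)
  x <- .check_matrix(x)
  if (identical(attr(x, "scale"), "log2")) x <- 2^x
  .check_sheet(sheet, colnames(x))
  key <- sheet[match(colnames(x), sheet$array_id), ]
  projects <- sort(unique(key$project))

  col_of <- function(strain, fraction, project) {
    j <- which(key$strain == strain & key$fraction == fraction &
                 key$project == project)
    if (length(j) != 1L)
      stop("design error: expected one ", fraction, " column for ", strain,
           " project ", project, call. = FALSE)
    j
  }
  if (any(x <= 0)) stop("data error: non-positive intensity", call. = FALSE)

  te <- list()
  for (s in c("WT", "mutant")) {
    tag <- if (s == "WT") "wt" else "mut"
    for (p in projects)
      te[[sprintf("te_%s_%s", tag, p)]] <-
        x[, col_of(s, numerator, p)] / x[, col_of(s, "T", p)]
  }
  wt_cols <- sprintf("te_wt_%s", projects)
  mut_cols <- sprintf("te_mut_%s", projects)
  te_wt <- do.call(cbind, te[wt_cols])
  te_mut <- do.call(cbind, te[mut_cols])

  if (pooled == "ratio_of_means") {
    num_wt <- rowMeans(x[, vapply(projects, function(p) col_of("WT", numerator, p), 1L), drop = FALSE])
    den_wt <- rowMeans(x[, vapply(projects, function(p) col_of("WT", "T", p), 1L), drop = FALSE])
    num_mut <- rowMeans(x[, vapply(projects, function(p) col_of("mutant", numerator, p), 1L), drop = FALSE])
    den_mut <- rowMeans(x[, vapply(projects, function(p) col_of("mutant", "T", p), 1L), drop = FALSE])
    mean_te_wt <- num_wt / den_wt
    mean_te_mut <- num_mut / den_mut
  } else {
    mean_te_wt <- rowMeans(te_wt)
    mean_te_mut <- rowMeans(te_mut)
  }

  ratios <- te_mut / te_wt
  mean_ratio <- rowMeans(ratios)
  ratio_sem <- apply(ratios, 1L, stats::sd) / sqrt(ncol(ratios))
  tt <- gene_ttest(te_mut, te_wt)

  out <- data.frame(gene_id = rownames(x), stringsAsFactors = FALSE)
  for (nm in c(wt_cols, mut_cols)) out[[nm]] <- te[[nm]]
  out$mean_te_wt <- mean_te_wt
  out$mean_te_mut <- mean_te_mut
  for (i in seq_along(projects)) out[[sprintf("ratio_%s", projects[i])]] <- ratios[, i]
  out$mean_ratio <- mean_ratio
  out$ratio_sem <- ratio_sem
  out$p_value <- tt$p_value
  out$p_adj <- stats::p.adjust(tt$p_value, "BH")
  out$degenerate <- tt$degenerate
  rownames(out) <- NULL
  attr(out, "projects") <- projects
  attr(out, "numerator") <- numerator
  attr(out, "pooled") <- pooled
  class(out) <- c("te_table", "data.frame")
  out
}

#' Two-tailed pooled-variance Student's t-test
#'
#' Vectorised two-sample Student's t-test with pooled variance and
#' `df = n1 + n2 - 2`, as used to test per-gene differences between the
#' mutant and wild-type per-project TE values. When both samples have zero
#' variance the test is degenerate; the p-value is then defined as 0 if the
#' means differ and 1 if they are equal, and flagged.
#'
#' @param a,b Numeric vectors (one gene), or matrices with one row per gene
#'   and one column per replicate; `n >= 2` in each sample.
#' @return A list: `statistic`, `df`, `p_value`, `degenerate` (logical).
#' @examples
#' gene_ttest(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.0213
#' @export
gene_ttest <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, 1L)
  if (is.null(dim(b))) b <- matrix(b, 1L)
  n1 <- ncol(a); n2 <- ncol(b)
  if (n1 < 2L || n2 < 2L)
    stop("statistics error: at least two replicates per sample", call. = FALSE)
  if (nrow(a) != nrow(b))
    stop("statistics error: samples must align row-wise", call. = FALSE)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- .row_var(a); v2 <- .row_var(b)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  df <- n1 + n2 - 2
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  degen <- se == 0
  if (any(degen)) {
    p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
    tstat[degen] <- ifelse(m1[degen] == m2[degen], 0, Inf * sign(m1 - m2)[degen])
  }
  list(statistic = tstat, df = df, p_value = p, degenerate = degen)
}

.row_var <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1)
}

#' Classify genes by TE ratio and significance
#'
#' Splits genes into a down-responsive set (mean mutant/WT TE ratio at or
#' below `down` with t-test p-value at or below `alpha`) and an
#' up-responsive set (mean ratio at or above `up`, same p condition).
#' Shrinking `alpha` or tightening the ratio thresholds can only remove
#' members.
#'
#' @param te A `te_table` from [compute_te()].
#' @param down,up Ratio thresholds (defaults 0.71 and 1.4); `down < up`
#'   required.
#' @param alpha P-value threshold (default 0.1).
#' @return An object of class `"te_classification"`: `down_set`, `up_set`
#'   (character vectors of gene ids) and the thresholds used.
#' @export
classify_genes <- function(te, down = 0.71, up = 1.4, alpha = 0.1) {
  if (down >= up)
    stop("configuration error: down threshold must be below up threshold",
         call. = FALSE)
  sig <- te$p_value <= alpha
  structure(list(
    down_set = te$gene_id[te$mean_ratio <= down & sig],
    up_set = te$gene_id[te$mean_ratio >= up & sig],
    down = down, up = up, alpha = alpha,
    n_genes = nrow(te)
  ), class = "te_classification")
}

#' @export
print.te_classification <- function(x, ...) {
  cat(sprintf("TE classification of %d genes (ratio <= %.3g or >= %.3g, p <= %.3g)\n",
              x$n_genes, x$down, x$up, x$alpha))
  cat(sprintf("  down-responsive: %d genes\n  up-responsive:   %d genes\n",
              length(x$down_set), length(x$up_set)))
  invisible(x)
}

#' Tabulate genes beyond TE thresholds
#'
#' Counts genes whose pooled mean TE is at least 1.5, at least 2.0, at most
#' 0.67, and at most 0.5 (inclusive comparisons), per strain.
#'
#' @param te A `te_table`, or a numeric vector of mean TEs (then a one-row
#'   table is returned).
#' @param high,higher,low,lower Thresholds.
#' @return An integer matrix, strains as rows, thresholds as columns.
#' @export
tabulate_thresholds <- function(te, high = 1.5, higher = 2.0,
                                low = 0.67, lower = 0.5) {
  count4 <- function(v) c(sum(v >= high), sum(v >= higher),
                          sum(v <= low), sum(v <= lower))
  labs <- c(sprintf("TE >= %.3g", c(high, higher)),
            sprintf("TE <= %.3g", c(low, lower)))
  if (is.numeric(te)) {
    m <- matrix(count4(te), 1L, dimnames = list("all", labs))
  } else {
    m <- rbind(`wild-type` = count4(te$mean_te_wt),
               mutant = count4(te$mean_te_mut))
    colnames(m) <- labs
  }
  m
}

#' Fractions of threshold-passing genes dependent on the wild-type factor
#'
#' Among genes with pooled mean wild-type TE at or above `high` (default
#' 1.5), the fraction also satisfying the strict condition TE_wt > TE_mut
#' (i.e. translated relatively better in wild type); and among genes with
#' mean TE_wt at or below `low` (default 0.67), both the fraction with
#' TE_wt > TE_mut and the complementary fraction with TE_wt < TE_mut are
#' reported, since either direction can be of interest for the low-TE set.
#'
#' @param te A `te_table`.
#' @param high,low TE thresholds for the two gene sets.
#' @return A list: `high_frac`, `low_frac_wt_gt`, `low_frac_wt_lt`,
#'   `n_high`, `n_low`. Fractions are `NA` (with a warning) for empty sets.
#' @export
dependency_fractions <- function(te, high = 1.5, low = 0.67) {
  hi <- te$mean_te_wt >= high
  lo <- te$mean_te_wt <= low
  if (!any(hi) || !any(lo))
    warning("statistics error: empty gene set; fraction undefined",
            call. = FALSE)
  frac <- function(cond, set) if (any(set)) mean(cond[set]) else NA_real_
  gt <- te$mean_te_wt > te$mean_te_mut
  list(high_frac = frac(gt, hi),
       low_frac_wt_gt = frac(gt, lo),
       low_frac_wt_lt = frac(te$mean_te_wt < te$mean_te_mut, lo),
       n_high = sum(hi), n_low = sum(lo))
}

#' MA statistics for a pair of arrays
#'
#' For two positive intensity vectors, computes per-gene
#' `M = log2(v1) - log2(v2)` and `A = 0.5 * (log2(v1) + log2(v2))`, and the
#' sample variance of M (denominator n - 1), the genome-wide summary of how
#' far the two arrays diverge.
#'
#' @param v1,v2 Positive intensity vectors of equal length >= 2.
#' @return A list of class `"ma_stats"`: `M`, `A`, `variance_M`, `n`.
#' @export
ma_stats <- function(v1, v2) {
  if (length(v1) != length(v2) || length(v1) < 2L)
    stop("statistics error: two equal-length vectors (n >= 2) required",
         call. = FALSE)
  if (any(v1 <= 0) || any(v2 <= 0))
    stop("data error: non-positive intensity", call. = FALSE)
  M <- log2(v1) - log2(v2)
  A <- 0.5 * (log2(v1) + log2(v2))
  structure(list(M = M, A = A, variance_M = stats::var(M), n = length(M)),
            class = "ma_stats")
}

#' @export
print.ma_stats <- function(x, ...) {
  cat(sprintf("MA statistics over %d genes: variance(M) = %.4g\n",
              x$n, x$variance_M))
  invisible(x)
}

#' Regression of wild-type on mutant log2 TE
#'
#' Ordinary least-squares fit of `log2(mean TE_wt)` on `log2(mean TE_mut)`
#' across all genes. A slope above 1 is the range-narrowing signature:
#' high-TE genes in wild type lose, and low-TE genes gain, efficiency in the
#' mutant. `response = "mut"` swaps the orientation.
#'
#' @param te A `te_table`.
#' @param response Which strain's log2 TE is the response (default `"wt"`).
#' @return A list of class `"te_regression"`: `slope`, `intercept`,
#'   `n_genes`, `response`, and the underlying `lm` fit (`fit`).
#' @export
te_regression <- function(te, response = c("wt", "mut")) {
  response <- match.arg(response)
  if (nrow(te) < 2L)
    stop("statistics error: at least two genes required", call. = FALSE)
  y <- log2(if (response == "wt") te$mean_te_wt else te$mean_te_mut)
  x <- log2(if (response == "wt") te$mean_te_mut else te$mean_te_wt)
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 n_genes = nrow(te), response = response, fit = fit),
            class = "te_regression")
}

#' @export
print.te_regression <- function(x, ...) {
  cat(sprintf("log2 TE regression (%s on %s), %d genes\n",
              x$response, setdiff(c("wt", "mut"), x$response), x$n_genes))
  cat(sprintf("  slope %.4g, intercept %.4g\n", x$slope, x$intercept))
  invisible(x)
}

#' Mean wild-type/mutant TE ratio of a TE stratum
#'
#' Per-gene per-project TE_wt/TE_mut ratios are averaged over projects, then
#' averaged over the genes whose pooled mean wild-type TE lies above (or
#' below) the genome-average wild-type TE (the arithmetic mean over all
#' genes).
#'
#' @param te A `te_table`.
#' @param selector `"above"` or `"below"` the genome-average TE_wt.
#' @return A list: `mean_ratio`, `n_genes`, `genome_mean_te_wt`.
#' @export
group_mean_ratio <- function(te, selector = c("above", "below")) {
  selector <- match.arg(selector)
  projects <- attr(te, "projects")
  wt <- as.matrix(te[sprintf("te_wt_%s", projects)])
  mut <- as.matrix(te[sprintf("te_mut_%s", projects)])
  per_gene <- rowMeans(wt / mut)
  gm <- mean(te$mean_te_wt)
  sel <- if (selector == "above") te$mean_te_wt > gm else te$mean_te_wt < gm
  if (!any(sel))
    stop("statistics error: empty selection", call. = FALSE)
  list(mean_ratio = mean(per_gene[sel]), n_genes = sum(sel),
       genome_mean_te_wt = gm)
}
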