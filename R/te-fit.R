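#' Fit the genome-wide translational-efficiency model
#'
#' The main entry point: runs the full analysis chain on a probe-level
#' intensity matrix — quantile normalization, log2 transform, median-polish
#' summarization to gene level, technical-replicate averaging, per-gene TE
#' computation — and derives the range-narrowing diagnostics: the OLS
#' regression of log2 wild-type TE on log2 mutant TE, per-project MA
#' variances of the polysomal:total comparison for each strain, threshold
#' counts, and the ratio-plus-t-test gene classification.
#'
#' Pass a gene-level matrix with `probe_map = NULL` to skip summarization
#' (the matrix is then expected to be one row per gene, linear scale unless
#' log2-flagged).
#'
#' @param x Probe-level (or gene-level) intensity matrix, arrays as columns.
#' @param sheet Sample sheet (`array_id`, `strain`, `fraction`, `project`,
#'   `tech_rep`) matching the columns of `x`.
#' @param probe_map `probe_id`/`gene_id` map for probe-level input, or
#'   `NULL` for gene-level input.
#' @param numerator Polysomal fraction used as the TE numerator.
#' @param normalize `"quantile"` (default) or `"none"`. Quantile
#'   normalization aligns the arrays' intensity distributions; switch it off
#'   for data already on a strictly common scale.
#' @param pooled Pooled-TE estimator, see [compute_te()].
#' @param down,up,alpha Classification thresholds, see [classify_genes()].
#' @param tech_rep_space Averaging scale for technical replicates.
#' @return An object of class `"te_fit"`: components `te` (the
#'   [compute_te()] table), `regression` ([te_regression()]),
#'   `ma_variances` (data.frame of per-project polysomal:total variance of M
#'   per strain), `thresholds` ([tabulate_thresholds()]), `classification`
#'   ([classify_genes()]), `dependency` ([dependency_fractions()]),
#'   `summarized` (gene x group matrix), `options`, `call`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_genes = 150, seed = 1))
#' fit <- te_fit(sim$matrix, sim$sheet, sim$probe_map)
#' coef(fit)
#' @export
te_fit <- function(x, sheet, probe_map = NULL,
                   numerator = c("HP", "LP"),
                   normalize = c("quantile", "none"),
                   pooled = c("ratio_of_means", "mean_of_ratios"),
                   down = 0.71, up = 1.4, alpha = 0.1,
                   tech_rep_space = c("linear", "log2")) {
  numerator <- match.arg(numerator)
  normalize <- match.arg(normalize)
  pooled <- match.arg(pooled)
  tech_rep_space <- match.arg(tech_rep_space)
  cl <- match.call()

  x <- .check_matrix(x)
  if (is.null(attr(x, "scale"))) attr(x, "scale") <- "linear"
  .check_sheet(sheet, colnames(x))
  if (normalize == "quantile") x <- quantile_normalize(x)

  if (!is.null(probe_map)) {
    if (identical(attr(x, "scale"), "linear")) {
      if (any(x <= 0)) stop("data error: non-positive intensity", call. = FALSE)
      x <- structure(log2(x), dimnames = dimnames(x), scale = "log2")
    }
    gene <- median_polish_summarize(x, probe_map)
  } else {
    gene <- x
  }
  summ <- summarize_tech_reps(gene, sheet, space = tech_rep_space)
  te <- compute_te(summ$matrix, summ$sheet, numerator = numerator,
                   pooled = pooled)

  # per-project polysomal:total MA variance, per strain
  lin <- if (identical(attr(summ$matrix, "scale"), "log2")) 2^summ$matrix else summ$matrix
  gs <- summ$sheet
  mav <- do.call(rbind, lapply(c("WT", "mutant"), function(s) {
    projects <- sort(unique(gs$project))
    data.frame(strain = s, project = projects,
               variance_M = vapply(projects, function(p) {
                 v1 <- lin[, gs$array_id[gs$strain == s & gs$fraction == numerator & gs$project == p]]
                 v2 <- lin[, gs$array_id[gs$strain == s & gs$fraction == "T" & gs$project == p]]
                 ma_stats(v1, v2)$variance_M
               }, numeric(1)), stringsAsFactors = FALSE)
  }))
  rownames(mav) <- NULL

  structure(list(
    te = te,
    regression = te_regression(te),
    ma_variances = mav,
    thresholds = tabulate_thresholds(te),
    classification = classify_genes(te, down = down, up = up, alpha = alpha),
    dependency = dependency_fractions(te),
    summarized = summ$matrix,
    group_sheet = gs,
    options = list(numerator = numerator, normalize = normalize,
                   pooled = pooled, down = down, up = up, alpha = alpha,
                   tech_rep_space = tech_rep_space),
    call = cl
  ), class = "te_fit")
}

#' @export
print.te_fit <- function(x, ...) {
  cat("Genome-wide translational-efficiency fit\n")
  cat(sprintf("  %d genes, numerator %s, normalization: %s\n",
              nrow(x$te), x$options$numerator, x$options$normalize))
  cat(sprintf("  log2 TE regression slope (WT on mutant): %.3f\n",
              x$regression$slope))
  cat(sprintf("  classified: %d down-responsive, %d up-responsive (ratio <= %.3g / >= %.3g, p <= %.3g)\n",
              length(x$classification$down_set), length(x$classification$up_set),
              x$options$down, x$options$up, x$options$alpha))
  invisible(x)
}

#' Summarize a translational-efficiency fit
#'
#' @param object A `te_fit`.
#' @param ... Unused.
#' @return A `summary.te_fit` list: regression slope/intercept, mean MA
#'   variance of the polysomal:total comparison per strain and their ratio,
#'   genome-mean TEs, threshold counts, classification sizes, dependency
#'   fractions.
#' @export
summary.te_fit <- function(object, ...) {
  mv <- object$ma_variances
  vwt <- mean(mv$variance_M[mv$strain == "WT"])
  vmut <- mean(mv$variance_M[mv$strain == "mutant"])
  structure(list(
    n_genes = nrow(object$te),
    slope = object$regression$slope,
    intercept = object$regression$intercept,
    variance_M_wt = vwt, variance_M_mut = vmut,
    variance_ratio = vwt / vmut,
    genome_mean_te_wt = mean(object$te$mean_te_wt),
    genome_mean_te_mut = mean(object$te$mean_te_mut),
    thresholds = object$thresholds,
    n_down = length(object$classification$down_set),
    n_up = length(object$classification$up_set),
    dependency = object$dependency,
    options = object$options
  ), class = "summary.te_fit")
}

#' @export
print.summary.te_fit <- function(x, ...) {
  cat("Genome-wide translational-efficiency analysis\n")
  cat(sprintf("  genes: %d\n", x$n_genes))
  cat(sprintf("  log2 TE regression: slope %.3f, intercept %.3g\n",
              x$slope, x$intercept))
  cat(sprintf("  variance of M (%s:T): WT %.4f, mutant %.4f (ratio %.2f)\n",
              x$options$numerator, x$variance_M_wt, x$variance_M_mut,
              x$variance_ratio))
  cat(sprintf("  genome-mean TE: WT %.3f, mutant %.3f\n",
              x$genome_mean_te_wt, x$genome_mean_te_mut))
  cat("  genes beyond TE thresholds:\n")
  print(x$thresholds)
  cat(sprintf("  classification: %d down, %d up (p <= %.3g)\n",
              x$n_down, x$n_up, x$options$alpha))
  if (!is.na(x$dependency$high_frac))
    cat(sprintf("  of %d genes with TE_wt >= 1.5, %.1f%% have TE_wt > TE_mut\n",
                x$dependency$n_high, 100 * x$dependency$high_frac))
  invisible(x)
}

#' @export
coef.te_fit <- function(object, ...) {
  c(intercept = object$regression$intercept, slope = object$regression$slope)
}

#' @export
residuals.te_fit <- function(object, ...) {
  stats::residuals(object$regression$fit)
}

#' Predict wild-type log2 TE from mutant log2 TE
#'
#' @param object A `te_fit`.
#' @param newdata Optional numeric vector of mutant log2 TE values (or a
#'   data.frame with column `x`); defaults to the fitted genes.
#' @param ... Unused.
#' @return Predicted response log2 TE values.
#' @export
predict.te_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::predict(object$regression$fit))
  if (is.numeric(newdata)) newdata <- data.frame(x = newdata)
  stats::predict(object$regression$fit, newdata = newdata)
}

#' Scatter plot of log2 TEs with the fitted regression line
#'
#' Mutant log2 TE on the x axis, wild-type on the y axis; the solid line is
#' the fitted regression, the dotted line the identity expected if TEs were
#' unchanged between strains.
#'
#' @param x A `te_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.te_fit <- function(x, ...) {
  lx <- log2(x$te$mean_te_mut)
  ly <- log2(x$te$mean_te_wt)
  graphics::plot(lx, ly, pch = ".", xlab = "log2 TE (mutant)",
                 ylab = "log2 TE (wild type)", ...)
  graphics::abline(x$regression$intercept, x$regression$slope)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
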