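#' Quantile normalization
#'
#' Forces every array (column) to share one intensity distribution: each
#' column's sorted values are replaced by the across-array mean of sorted
#' columns, reassigned by rank. Within-column rank order is preserved; tied
#' values receive the mean of the tied reference values.
#'
#' @param x Numeric matrix (probes/genes x arrays), no missing values. A
#'   `"scale"` attribute (`"linear"` or `"log2"`), if present, is preserved.
#' @return Matrix of the same shape with identical column distributions.
#' @examples
#' quantile_normalize(cbind(a = c(1, 2, 3), b = c(4, 2, 6)))
#' @export
quantile_normalize <- function(x) {
  x <- .check_matrix(x)
  if (anyNA(x)) stop("data error: missing values not allowed", call. = FALSE)
  if (ncol(x) == 1L) return(x)
  ref <- rowMeans(apply(x, 2L, sort, method = "quick"))
  out <- x
  for (j in seq_len(ncol(x))) {
    v <- numeric(nrow(x))
    v[order(x[, j])] <- ref
    # ties: each tie group gets the mean of its reference values
    out[, j] <- stats::ave(v, match(x[, j], x[, j]), FUN = mean)
  }
  attr(out, "scale") <- attr(x, "scale")
  out
}

#' Median-polish (RMA-style) probe summarization
#'
#' Summarizes log2 probe-level intensities to one value per gene per array by
#' fitting the additive model `log2 I = mu + probe effect + array effect +
#' residual` with Tukey's median polish: alternating row and column median
#' sweeps until the sum of absolute residuals changes by at most a relative
#' `tol`, or `max_iter` sweeps. The per-array summary is `mu + array effect`
#' (probe effects are discarded), as in the RMA summarization step.
#'
#' @param x Log2-scale probe x array matrix (attribute `scale = "log2"`, or
#'   pass `force = TRUE` for an unflagged log2 matrix).
#' @param probe_map Data frame mapping `probe_id` to `gene_id`; every row of
#'   `x` must map to exactly one gene. Genes in the map with no probe rows
#'   are omitted with a warning.
#' @param tol Convergence tolerance on the residual sum (relative).
#' @param max_iter Maximum number of sweep iterations.
#' @param residuals Also return the probe-level residual matrix?
#' @param force Skip the log2 scale-flag check.
#' @return Gene x array matrix (`scale = "log2"`), rownames gene ids, genes
#'   in first-appearance order. If `residuals = TRUE`, the residual matrix is
#'   attached as attribute `"residuals"`.
#' @export
median_polish_summarize <- function(x, probe_map, tol = 1e-6, max_iter = 20L,
                                    residuals = FALSE, force = FALSE) {
  x <- .check_matrix(x)
  sc <- attr(x, "scale")
  if (!force && !identical(sc, "log2"))
    stop("scale error: median polish requires a log2-flagged matrix", call. = FALSE)
  ids <- rownames(x)
  if (is.null(ids)) ids <- probe_map$probe_id[seq_len(nrow(x))]
  idx <- match(ids, probe_map$probe_id)
  if (anyNA(idx))
    stop("data error: probes without a gene mapping: ",
         paste(utils::head(ids[is.na(idx)], 3L), collapse = ", "), call. = FALSE)
  genes <- unique(probe_map$gene_id)
  grp <- match(probe_map$gene_id[idx], genes)
  fit <- .medpolish_groups(x, grp, length(genes), tol, as.integer(max_iter),
                           isTRUE(residuals))
  out <- fit$summaries
  dimnames(out) <- list(genes, colnames(x))
  if (any(rowSums(is.na(out)) > 0L)) {
    dropped <- genes[rowSums(is.na(out)) > 0L]
    warning("omitting ", length(dropped), " gene(s) with zero probes: ",
            paste(utils::head(dropped, 3L), collapse = ", "), call. = FALSE)
    out <- out[!rownames(out) %in% dropped, , drop = FALSE]
  }
  attr(out, "scale") <- "log2"
  if (isTRUE(residuals)) {
    res <- fit$residuals
    dimnames(res) <- dimnames(x)
    attr(out, "residuals") <- res
  }
  out
}

#' Average technical replicate arrays
#'
#' Collapses the arrays of each (strain, fraction, project) group to a single
#' column by the arithmetic mean of the technical-replicate intensities on
#' the linear scale. Log2-flagged input is converted to linear, averaged,
#' and re-flagged (note `mean(2^x) != 2^mean(x)`); set `space = "log2"` to
#' average log2 values directly instead.
#'
#' @param x Gene x array matrix with a `"scale"` attribute.
#' @param sheet Sample sheet with `array_id`, `strain`, `fraction`,
#'   `project`, `tech_rep`; `array_id` must cover all columns of `x`.
#' @param space Averaging scale, `"linear"` (default) or `"log2"`.
#' @return A list: `matrix` (gene x group, scale matching the input flag) and
#'   `sheet` (one row per group: `array_id` = group id, `strain`, `fraction`,
#'   `project`).
#' @export
summarize_tech_reps <- function(x, sheet, space = c("linear", "log2")) {
  space <- match.arg(space)
  x <- .check_matrix(x)
  sc <- attr(x, "scale")
  .check_sheet(sheet, colnames(x))
  key <- sheet[match(colnames(x), sheet$array_id), ]
  grp <- paste(key$strain, key$fraction, key$project, sep = "_")
  groups <- unique(grp)
  is_log <- identical(sc, "log2")
  lin <- if (is_log && space == "linear") 2^x else x
  out <- matrix(0, nrow(x), length(groups),
                dimnames = list(rownames(x), groups))
  for (g in seq_along(groups)) {
    cols <- which(grp == groups[g])
    if (length(cols) == 0L) stop("data error: empty replicate group", call. = FALSE)
    out[, g] <- rowMeans(lin[, cols, drop = FALSE])
  }
  if (is_log && space == "linear") out <- log2(out)
  attr(out, "scale") <- sc
  gs <- key[!duplicated(grp), c("strain", "fraction", "project")]
  gs <- data.frame(array_id = groups, gs, row.names = NULL,
                   stringsAsFactors = FALSE)
  list(matrix = out, sheet = gs)
}

.check_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("data error: a numeric matrix is required", call. = FALSE)
  if (ncol(x) < 1L) stop("data error: at least one array required", call. = FALSE)
  x
}

.check_sheet <- function(sheet, array_ids) {
  need <- c("array_id", "strain", "fraction", "project")
  miss <- setdiff(need, names(sheet))
  if (length(miss))
    stop("data error: sample sheet lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  absent <- setdiff(array_ids, sheet$array_id)
  if (length(absent))
    stop("consistency error: arrays missing from sample sheet: ",
         paste(utils::head(absent, 3L), collapse = ", "), call. = FALSE)
  invisible(sheet)
}
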