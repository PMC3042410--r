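#' Read and write expression matrix TSV files
#'
#' The matrix dialect is tab-separated UTF-8 with a header row, optional
#' `#`-prefixed comment lines, and the intensity scale recorded in a leading
#' `#scale=linear` or `#scale=log2` line. The first column is `probe_id`
#' (or `gene_id` for gene-level matrices); probe-level files carry a second
#' `gene_id` column; remaining columns are arrays. Malformed input (ragged
#' rows, duplicate ids, non-numeric cells) is reported with line numbers.
#'
#' @param path File path.
#' @return `read_matrix()`: a list with `matrix` (numeric, `"scale"`
#'   attribute, rownames = ids) and `probe_map` (`NULL` for gene-level
#'   files). `write_matrix()`: the path, invisibly.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  scale_line <- grep("^#scale=", lines)
  scale <- if (length(scale_line)) sub("^#scale=", "", lines[scale_line[1L]]) else "linear"
  if (!scale %in% c("linear", "log2"))
    stop("parse error: unknown scale '", scale, "'", call. = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  body <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (length(body) < 2L) stop("parse error: no data rows", call. = FALSE)
  header <- body[[1L]]
  nf <- lengths(body)
  if (any(nf != length(header))) {
    bad <- lineno[which(nf != length(header))[1L]]
    stop("parse error: ragged row at line ", bad, call. = FALSE)
  }
  has_map <- length(header) >= 2L && identical(header[1:2], c("probe_id", "gene_id"))
  id_cols <- if (has_map) 2L else 1L
  rows <- body[-1L]
  ids <- vapply(rows, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    bad <- lineno[-1L][which(duplicated(ids))[1L]]
    stop("parse error: duplicate id '", ids[duplicated(ids)][1L],
         "' at line ", bad, call. = FALSE)
  }
  vals <- matrix(NA_real_, length(rows), length(header) - id_cols)
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]][-seq_len(id_cols)]))
    if (anyNA(v))
      stop("parse error: non-numeric cell at line ", lineno[-1L][i], call. = FALSE)
    vals[i, ] <- v
  }
  dimnames(vals) <- list(ids, header[-seq_len(id_cols)])
  attr(vals, "scale") <- scale
  probe_map <- if (has_map)
    data.frame(probe_id = ids,
               gene_id = vapply(rows, `[[`, "", 2L),
               stringsAsFactors = FALSE) else NULL
  list(matrix = vals, probe_map = probe_map)
}

#' @rdname read_matrix
#' @param x Numeric matrix with rownames (ids) and a `"scale"` attribute.
#' @param probe_map Optional `probe_id`/`gene_id` map matching the rownames.
#' @export
write_matrix <- function(x, path, probe_map = NULL) {
  sc <- attr(x, "scale")
  if (is.null(sc)) sc <- "linear"
  ids <- rownames(x)
  if (is.null(ids)) stop("data error: matrix must have rownames", call. = FALSE)
  if (is.null(probe_map)) {
    header <- c("gene_id", colnames(x))
    left <- ids
  } else {
    header <- c("probe_id", "gene_id", colnames(x))
    left <- paste(ids, probe_map$gene_id[match(ids, probe_map$probe_id)],
                  sep = "\t")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#scale=%s", sc), con)
  writeLines(paste(header, collapse = "\t"), con)
  writeLines(paste(left, apply(x, 1L, function(r)
    paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = "\t")), sep = "\t"), con)
  invisible(path)
}

.read_tsv <- function(path, required, name) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop("parse error: ", name, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  d
}

#' Read a sample sheet TSV
#'
#' Columns: `array_id`, `strain`, `fraction`, `project`, `tech_rep`.
#'
#' @param path File path.
#' @return A `data.frame`.
#' @export
read_sheet <- function(path) {
  d <- .read_tsv(path, c("array_id", "strain", "fraction", "project", "tech_rep"),
                 "sample sheet")
  if (anyDuplicated(d$array_id))
    stop("parse error: duplicate array_id in sample sheet", call. = FALSE)
  d
}

#' Read a gene feature table TSV
#'
#' Requires `gene_id`; recognised annotation columns are `utr5_len`,
#' `orf_len`, `utr3_len`, `n_uorfs`, `mfe_significant`, `essential`,
#' `category`, `ribosome_density`, `peak_ribosomes` (all optional; missing
#' values permitted).
#'
#' @param path File path.
#' @return A `data.frame`.
#' @export
read_features <- function(path) {
  d <- .read_tsv(path, "gene_id", "feature table")
  if (anyDuplicated(d$gene_id))
    stop("parse error: duplicate gene_id in feature table", call. = FALSE)
  for (col in c("mfe_significant", "essential"))
    if (col %in% names(d)) d[[col]] <- as.logical(d[[col]])
  d
}

#' Read a qPCR Ct table TSV
#'
#' Columns: `gene_id`, `strain`, `fraction`, `target`, `replicate`, `ct`.
#'
#' @param path File path.
#' @return A `data.frame`.
#' @export
read_ct <- function(path) {
  d <- .read_tsv(path, c("gene_id", "strain", "fraction", "target",
                         "replicate", "ct"), "Ct table")
  if (!is.numeric(d$ct))
    stop("parse error: non-numeric ct column", call. = FALSE)
  d
}

#' Run the complete analysis pipeline on files
#'
#' Reads a probe (or gene) matrix and sample sheet, fits the TE model with
#' [te_fit()], optionally runs the feature associations, writes the TE
#' table, classification and a JSON report to `out_dir`, and returns the
#' report. Reports are deterministic: rerunning on identical inputs gives a
#' byte-identical report file.
#'
#' @param matrix_file Probe/gene matrix TSV (see [read_matrix()]).
#' @param sheet_file Sample sheet TSV.
#' @param feature_file Optional feature table TSV.
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing.
#' @param ... Passed to [te_fit()] (thresholds, normalization, ...).
#' @return The report, an object of class `"te_report"` (a nested list),
#'   invisibly containing the `te_fit` as attribute `"fit"`.
#' @export
run_pipeline <- function(matrix_file, sheet_file, feature_file = NULL,
                         out_dir = NULL, ...) {
  m <- read_matrix(matrix_file)
  sheet <- read_sheet(sheet_file)
  fit <- te_fit(m$matrix, sheet, probe_map = m$probe_map, ...)
  s <- summary(fit)
  report <- list(
    inputs = list(matrix_file = basename(matrix_file),
                  sheet_file = basename(sheet_file),
                  n_probes = nrow(m$matrix), n_arrays = ncol(m$matrix)),
    options = fit$options,
    n_genes = s$n_genes,
    regression = list(slope = s$slope, intercept = s$intercept),
    ma_variance = list(wt = s$variance_M_wt, mutant = s$variance_M_mut,
                       ratio = s$variance_ratio),
    genome_mean_te = list(wt = s$genome_mean_te_wt, mutant = s$genome_mean_te_mut),
    threshold_counts = as.data.frame(as.table(s$thresholds)),
    classification = list(n_down = s$n_down, n_up = s$n_up,
                          down_set = fit$classification$down_set,
                          up_set = fit$classification$up_set),
    dependency_fractions = s$dependency
  )
  if (!is.null(feature_file)) {
    features <- read_features(feature_file)
    assoc <- function(set) {
      if (length(set) < 2L) return(NULL)
      out <- list()
      for (f in intersect(c("utr5_len", "orf_len", "utr3_len"), names(features)))
        out[[f]] <- group_feature_stats(set, features, f)[c("mean", "sem", "p_value")]
      if ("n_uorfs" %in% names(features))
        out$n_uorfs <- uorf_stats(set, features)[c("mean", "sem", "p_value")]
      if ("essential" %in% names(features))
        out$essential <- essential_fraction(set, features)[c("fraction", "fisher_p")]
      out
    }
    report$features <- list(down_set = assoc(fit$classification$down_set),
                            up_set = assoc(fit$classification$up_set))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(fit$te, file.path(out_dir, "te_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(report, class = "te_report", fit = fit)
}

#' @export
print.te_report <- function(x, ...) {
  cat("Pipeline report:", x$n_genes, "genes,",
      sprintf("slope %.3f,", x$regression$slope),
      sprintf("%d down / %d up classified\n",
              x$classification$n_down, x$classification$n_up))
  invisible(x)
}

#' Write a synthetic dataset to TSV files
#'
#' Writes the probe matrix, sample sheet, feature table and truth table of a
#' [simulate_dataset()] result into a directory, in the formats the readers
#' of this package consume.
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Named vector of the written paths, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "probe_matrix.tsv"),
             sheet = file.path(dir, "sample_sheet.tsv"),
             features = file.path(dir, "features.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_matrix(sim$matrix, paths[["matrix"]], probe_map = sim$probe_map)
  utils::write.table(sim$sheet, paths[["sheet"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$features, paths[["features"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
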