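#' Simulate a per-gene structural feature table
#'
#' Draws gene features from genome-wide distributions matching published
#' compilations for budding yeast: 5'UTR lengths log-normal with mean 89 nt,
#' ORF lengths log-normal (mean ~1.4 kb), 3'UTR lengths log-normal (mean
#' ~120 nt), upstream ORF counts Poisson with rate 0.36 per transcript, an
#' essential-gene flag (~18% of genes), a rare strong-5'UTR-structure (MFE
#' significance) flag, a functional-category label, and a ribosome density
#' (ribosomes per 100 nt, centred on the genome average of 0.64 and inversely
#' related to ORF length) with the implied peak ribosome occupancy per mRNA.
#'
#' @param config A [sim_config()] object.
#' @return A `data.frame` with one row per gene: `gene_id`, `utr5_len`,
#'   `orf_len`, `utr3_len`, `n_uorfs`, `mfe_significant`, `essential`,
#'   `category`, `ribosome_density`, `peak_ribosomes`.
#' @seealso [simulate_true_te()], [simulate_probe_intensities()]
#' @export
simulate_features <- function(config) {
  stopifnot(inherits(config, "te_sim_config"))
  fp <- config$feature_params
  n <- config$n_genes
  set.seed(.stage_seed(config, "features"))

  rlen <- function(mean_nt, sdlog) {
    meanlog <- log(mean_nt) - sdlog^2 / 2
    pmax(1L, as.integer(round(stats::rlnorm(n, meanlog, sdlog))))
  }
  utr5 <- rlen(fp$utr5_mean, fp$utr5_sdlog)
  orf <- pmax(75L, as.integer(round(stats::rlnorm(n, fp$orf_meanlog, fp$orf_sdlog))))
  orf <- as.integer(3L * round(orf / 3))  # codon multiples
  utr3 <- rlen(fp$utr3_mean, fp$utr3_sdlog)
  uorfs <- stats::rpois(n, fp$uorf_rate)

  density <- fp$density_mean *
    (orf / stats::median(orf))^fp$density_orf_exp *
    exp(stats::rnorm(n, -fp$density_sdlog^2 / 2, fp$density_sdlog))

  data.frame(
    gene_id = sprintf("G%05d", seq_len(n)),
    utr5_len = utr5, orf_len = orf, utr3_len = utr3,
    n_uorfs = as.integer(uorfs),
    mfe_significant = stats::runif(n) < fp$mfe_frac,
    essential = stats::runif(n) < fp$essential_frac,
    category = sprintf("C%02d", sample.int(fp$n_categories, n, replace = TRUE)),
    ribosome_density = density,
    peak_ribosomes = pmax(1L, as.integer(round(density * orf / 100))),
    stringsAsFactors = FALSE
  )
}

#' Simulate true translational efficiencies
#'
#' Draws each gene's true log2 TE in wild type as Gaussian (SD `sigma_te`)
#' plus a linear coupling to centred log2 ORF length (negative by default,
#' reproducing the inverse TE/ORF-length relationship), then centres the
#' genome so the mean log2 TE is exactly 0 (the consequence of arrays being
#' scaled to a common average intensity). The mutant's log2 TE is the
#' wild-type value compressed by `beta`:
#' `log2 TE_mut = beta * log2 TE_wt`, so `beta < 1` narrows the TE range.
#' Total mRNA abundances are log-normal.
#'
#' @param config A [sim_config()] object.
#' @param features Feature table from [simulate_features()].
#' @return A truth table `data.frame`: `gene_id`, `true_log2_te_wt`,
#'   `true_log2_te_mut`, `true_abundance`, plus all feature columns.
#' @export
simulate_true_te <- function(config, features) {
  stopifnot(inherits(config, "te_sim_config"))
  if (nrow(features) != config$n_genes)
    stop("consistency error: feature table must have n_genes rows", call. = FALSE)
  n <- config$n_genes
  set.seed(.stage_seed(config, "truth"))

  l2orf <- log2(features$orf_len)
  raw <- stats::rnorm(n, 0, config$sigma_te) +
    config$orf_te_coupling * (l2orf - mean(l2orf))
  wt <- raw - mean(raw)
  mut <- config$beta * wt

  ab <- config$abundance_params
  abundance <- 2^stats::rnorm(n, ab$meanlog2, ab$sdlog2)

  cbind(
    data.frame(gene_id = features$gene_id,
               true_log2_te_wt = wt, true_log2_te_mut = mut,
               true_abundance = abundance, stringsAsFactors = FALSE),
    features[setdiff(names(features), "gene_id")]
  )
}

# Array inventory for a design: one array per strain x fraction x project x rep.
.array_design <- function(config) {
  fractions <- if (config$with_lp) c("HP", "LP", "T") else c("HP", "T")
  d <- expand.grid(
    tech_rep = seq_len(config$n_tech_reps),
    project = as.roman(seq_len(config$n_projects)),
    fraction = fractions,
    strain = c("WT", "mutant"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  d$project <- as.character(d$project)
  d <- d[, c("strain", "fraction", "project", "tech_rep")]
  d$array_id <- sprintf("%s_%s_%s_r%d", d$strain, d$fraction, d$project, d$tech_rep)
  d[, c("array_id", "strain", "fraction", "project", "tech_rep")]
}

#' Simulate probe-level array intensities
#'
#' Generates one array per strain x fraction x project x technical replicate.
#' The expected linear intensity of gene g on a total-RNA (T) array is its
#' abundance; on a polysomal (HP or LP) array it is abundance times the
#' strain's true TE. Each probe multiplies in a fixed affinity offset; each
#' RNA sample adds biological log2 noise shared by its technical replicates;
#' each probe measurement adds technical log2 noise; each array carries a
#' global scale factor. All noise is log-normal (additive on log2).
#'
#' @param config A [sim_config()] object.
#' @param truth Truth table from [simulate_true_te()].
#' @return A list: `matrix` (linear-scale probe x array intensity matrix with
#'   a `"scale"` attribute, rownames probe ids), `probe_map` (`probe_id`,
#'   `gene_id`), and `sheet` (the sample sheet, one row per array column).
#' @export
simulate_probe_intensities <- function(config, truth) {
  stopifnot(inherits(config, "te_sim_config"))
  if (nrow(truth) != config$n_genes)
    stop("consistency error: truth table must have n_genes rows", call. = FALSE)
  n <- config$n_genes; k <- config$probes_per_gene
  sheet <- .array_design(config)
  na <- nrow(sheet)
  set.seed(.stage_seed(config, "probes"))

  affinity <- stats::rnorm(n * k, 0, config$sigma_probe)
  scale_a <- stats::rnorm(na, 0, config$sigma_scale)

  # biological noise: one draw per gene per RNA sample (strain x fraction x project)
  sample_key <- paste(sheet$strain, sheet$fraction, sheet$project, sep = "_")
  samples <- unique(sample_key)
  bio <- matrix(stats::rnorm(n * length(samples), 0, config$sigma_bio),
                n, length(samples), dimnames = list(NULL, samples))

  gene_idx <- rep(seq_len(n), each = k)
  base_ab <- log2(truth$true_abundance)[gene_idx]
  te_wt <- truth$true_log2_te_wt[gene_idx]
  te_mut <- truth$true_log2_te_mut[gene_idx]

  m <- matrix(0, n * k, na)
  for (a in seq_len(na)) {
    l2 <- base_ab + affinity + scale_a[a]
    if (sheet$fraction[a] != "T")
      l2 <- l2 + if (sheet$strain[a] == "WT") te_wt else te_mut
    l2 <- l2 + bio[gene_idx, sample_key[a]]
    if (config$sigma_tech > 0)
      l2 <- l2 + stats::rnorm(n * k, 0, config$sigma_tech)
    m[, a] <- 2^l2
  }
  probe_id <- sprintf("%s_p%d", truth$gene_id[gene_idx], rep(seq_len(k), n))
  dimnames(m) <- list(probe_id, sheet$array_id)
  attr(m, "scale") <- "linear"
  list(matrix = m,
       probe_map = data.frame(probe_id = probe_id,
                              gene_id = truth$gene_id[gene_idx],
                              stringsAsFactors = FALSE),
       sheet = sheet)
}

#' Simulate a qPCR Ct table with known polysome distributions
#'
#' Constructs cycle-threshold values whose fraction-weighted 2^-ddCt
#' quantification reproduces the configured per-gene distribution of mRNA
#' across the Mono/LP/HP gradient pools. The 18S reference Ct is held at 15
#' cycles and the total-RNA gene-of-interest Ct at 25; the per-fraction Ct is
#' then set to `ct_total - log2(p_f / w_f)` for target proportion `p_f` and
#' A280 weight `w_f`, so that `2^-ddCt * w_f`, normalized, returns `p_f`
#' exactly when `sigma_ct = 0`. Triplicate technical replicates add Gaussian
#' Ct noise of SD `config$sigma_ct`.
#'
#' @param config A [sim_config()] object (`sigma_ct` sets the Ct noise).
#' @param truth Truth table (supplies gene ids), or a character vector of ids.
#' @param weights A280 fraction-weight set, see [a280_weights()].
#' @param props Target proportions: named numeric (`Mono`, `LP`, `HP`) used
#'   for every gene, or a matrix with one row per gene; rows must sum to 1.
#' @param strain Strain label recorded in the table.
#' @param n_replicates Technical qPCR replicates per well.
#' @return A `data.frame` Ct table: `gene_id`, `strain`, `fraction`
#'   (Mono/LP/HP/Total), `target` (GOI/18S), `replicate`, `ct`.
#' @seealso [polysome_profile()] for the recovery path.
#' @export
simulate_ct_table <- function(config, truth, weights = a280_weights(),
                              props = c(Mono = 1/3, LP = 1/3, HP = 1/3),
                              strain = "WT", n_replicates = 3L) {
  stopifnot(inherits(config, "te_sim_config"))
  gene_id <- if (is.character(truth)) truth else truth$gene_id
  w <- .strain_weights(weights, strain)
  if (is.null(dim(props))) {
    props <- matrix(props[c("Mono", "LP", "HP")], nrow = length(gene_id),
                    ncol = 3, byrow = TRUE, dimnames = list(NULL, c("Mono", "LP", "HP")))
  } else {
    props <- as.matrix(props)[, c("Mono", "LP", "HP"), drop = FALSE]
  }
  if (nrow(props) != length(gene_id))
    stop("consistency error: one proportion row per gene required", call. = FALSE)
  if (any(props <= 0) || any(abs(rowSums(props) - 1) > 1e-8))
    stop("configuration error: proportions must be positive and sum to 1", call. = FALSE)
  set.seed(.stage_seed(config, "ct"))

  ct_ref <- 15; ct_total <- 25
  fractions <- c("Mono", "LP", "HP")
  rows <- vector("list", length(fractions) + 1L)
  for (f in seq_along(fractions)) {
    ct_f <- ct_total - log2(props[, fractions[f]] / w[[fractions[f]]])
    rows[[f]] <- data.frame(gene_id = rep(gene_id, each = 2L * n_replicates),
                            strain = strain,
                            fraction = fractions[f],
                            target = rep(rep(c("GOI", "18S"), each = n_replicates),
                                         length(gene_id)),
                            replicate = rep(seq_len(n_replicates), 2L * length(gene_id)),
                            ct = as.vector(t(cbind(
                              matrix(rep(ct_f, n_replicates), ncol = n_replicates),
                              matrix(ct_ref, length(gene_id), n_replicates)))),
                            stringsAsFactors = FALSE)
  }
  rows[[length(fractions) + 1L]] <- data.frame(
    gene_id = rep(gene_id, each = 2L * n_replicates), strain = strain,
    fraction = "Total",
    target = rep(rep(c("GOI", "18S"), each = n_replicates), length(gene_id)),
    replicate = rep(seq_len(n_replicates), 2L * length(gene_id)),
    ct = rep(rep(c(ct_total, ct_ref), each = n_replicates), length(gene_id)),
    stringsAsFactors = FALSE)
  ct <- do.call(rbind, rows)
  if (config$sigma_ct > 0)
    ct$ct <- ct$ct + stats::rnorm(nrow(ct), 0, config$sigma_ct)
  rownames(ct) <- NULL
  ct
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [simulate_features()], [simulate_true_te()]
#' and [simulate_probe_intensities()] for one configuration.
#'
#' @param config A [sim_config()] object.
#' @return A list: `config`, `features`, `truth`, `matrix`, `probe_map`,
#'   `sheet`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  features <- simulate_features(config)
  truth <- simulate_true_te(config, features)
  probes <- simulate_probe_intensities(config, truth)
  c(list(config = config, features = features, truth = truth), probes)
}
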