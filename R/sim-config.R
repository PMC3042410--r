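#' Simulation configuration for a synthetic polysome-profiling study
#'
#' Defines the study design and generative parameters for the synthetic-data
#' module. Defaults emulate a genome-wide yeast polysome-profiling experiment:
#' ~6000 genes assayed in two strains (wild type and a translation-initiation
#' mutant) across three biological projects, each hybridized to three
#' technical replicate arrays, for the heavy-polysome (HP) and total (T) RNA
#' pools (light polysomes, LP, optional).
#'
#' The central parameter is `beta`, the compression factor applied to
#' log2 translational efficiency (TE) in the mutant: `log2 TE_mut =
#' beta * log2 TE_wt`. `beta < 1` narrows the genome-wide TE range, the
#' signature this package is built to detect; the default `1/1.30` makes the
#' wild-type-on-mutant regression slope of log2 TEs equal to 1.30 in the
#' noise-free limit.
#'
#' Noise is additive on the log2 scale at three levels: `sigma_bio` per RNA
#' sample (one independent draw per gene for each strain x fraction x project
#' preparation, capturing culture and gradient-fractionation variability),
#' `sigma_tech` per probe per array, and `sigma_probe` for fixed
#' multiplicative probe affinities. `sigma_scale` draws one global scale
#' offset per array (what quantile normalization removes). See the methods
#' vignette for how the default magnitudes were chosen.
#'
#' @param n_genes Number of simulated genes.
#' @param probes_per_gene Probes per gene on each array.
#' @param n_projects Number of biological replicates ("projects").
#' @param n_tech_reps Technical replicate arrays per RNA sample.
#' @param beta Compression factor on log2 TE in the mutant (>= 0).
#' @param sigma_te SD of log2 true TE across genes in wild type.
#' @param sigma_bio SD of per-sample biological log2 noise.
#' @param sigma_tech SD of per-probe, per-array technical log2 noise.
#' @param sigma_probe SD of fixed probe-affinity log2 offsets.
#' @param sigma_scale SD of per-array global log2 scale offsets.
#' @param sigma_ct SD (cycles) of qPCR Ct replicate noise.
#' @param abundance_params Log-normal parameters (`meanlog2`, `sdlog2`) for
#'   total mRNA abundance on the linear intensity scale.
#' @param orf_te_coupling Slope tying log2 TE_wt to centred log2 ORF length;
#'   negative values reproduce the inverse TE/ORF-length relationship.
#' @param feature_params List of feature-distribution parameters:
#'   `utr5_mean` (nt), `utr5_sdlog`, `orf_meanlog`, `orf_sdlog`, `utr3_mean`
#'   (nt), `utr3_sdlog`, `uorf_rate` (uORFs per transcript),
#'   `essential_frac`, `mfe_frac`, `n_categories`, `density_mean`
#'   (ribosomes per 100 nt), `density_sdlog`, `density_orf_exp`.
#' @param with_lp Also simulate light-polysome (LP) arrays?
#' @param seed Integer seed; identical configurations give identical output.
#' @return An object of class `"te_sim_config"` (a validated list).
#' @examples
#' cfg <- sim_config(n_genes = 100, seed = 1)
#' feats <- simulate_features(cfg)
#' @export
sim_config <- function(n_genes = 6000L,
                       probes_per_gene = 4L,
                       n_projects = 3L,
                       n_tech_reps = 3L,
                       beta = 1 / 1.30,
                       sigma_te = 0.55,
                       sigma_bio = 0.10,
                       sigma_tech = 0.10,
                       sigma_probe = 0.25,
                       sigma_scale = 0.05,
                       sigma_ct = 0.1,
                       abundance_params = list(meanlog2 = 8, sdlog2 = 1.2),
                       orf_te_coupling = -0.20,
                       feature_params = list(),
                       with_lp = FALSE,
                       seed = 1L) {
  fp <- utils::modifyList(list(
    utr5_mean = 89, utr5_sdlog = 0.8,
    orf_meanlog = log(1200), orf_sdlog = 0.55,
    utr3_mean = 120, utr3_sdlog = 0.6,
    uorf_rate = 0.36,
    essential_frac = 0.18,
    mfe_frac = 0.005,
    n_categories = 12L,
    density_mean = 0.64, density_sdlog = 0.35, density_orf_exp = -0.3
  ), feature_params)

  cfg <- list(
    n_genes = as.integer(n_genes), probes_per_gene = as.integer(probes_per_gene),
    n_projects = as.integer(n_projects), n_tech_reps = as.integer(n_tech_reps),
    beta = beta, sigma_te = sigma_te, sigma_bio = sigma_bio,
    sigma_tech = sigma_tech, sigma_probe = sigma_probe,
    sigma_scale = sigma_scale, sigma_ct = sigma_ct,
    abundance_params = abundance_params, orf_te_coupling = orf_te_coupling,
    feature_params = fp, with_lp = isTRUE(with_lp), seed = as.integer(seed)
  )
  counts <- c(n_genes = cfg$n_genes, probes_per_gene = cfg$probes_per_gene,
              n_projects = cfg$n_projects, n_tech_reps = cfg$n_tech_reps)
  if (any(is.na(counts)) || any(counts < 1L))
    stop("configuration error: all design counts must be >= 1", call. = FALSE)
  sds <- c(sigma_te = sigma_te, sigma_bio = sigma_bio, sigma_tech = sigma_tech,
           sigma_probe = sigma_probe, sigma_scale = sigma_scale,
           sigma_ct = sigma_ct)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("configuration error: all noise SDs must be finite and >= 0", call. = FALSE)
  if (!is.finite(beta) || beta < 0)
    stop("configuration error: beta must be >= 0", call. = FALSE)
  if (is.na(cfg$seed)) stop("configuration error: seed must be an integer", call. = FALSE)
  structure(cfg, class = "te_sim_config")
}

#' @export
print.te_sim_config <- function(x, ...) {
  cat("Synthetic polysome-profiling design\n")
  cat(sprintf("  %d genes x %d probes; %d projects x %d technical replicates\n",
              x$n_genes, x$probes_per_gene, x$n_projects, x$n_tech_reps))
  cat(sprintf("  fractions: %s; strains: WT, mutant\n",
              if (x$with_lp) "HP, LP, T" else "HP, T"))
  cat(sprintf("  beta = %.4g, sigma_te = %.3g, noise (bio/tech/probe/scale) = %.3g/%.3g/%.3g/%.3g\n",
              x$beta, x$sigma_te, x$sigma_bio, x$sigma_tech, x$sigma_probe, x$sigma_scale))
  cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}

# Deterministic sub-stream seeding: each generator stage draws from its own
# stream derived from (config seed, stage offset), so stages are independently
# reproducible. Kept below 2^31 - 1.
.stage_seed <- function(config, stage) {
  offs <- c(features = 11L, truth = 23L, probes = 37L, ct = 53L)
  (config$seed %% 1000000L) * 1000L + offs[[stage]]
}
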