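# Small shared fixtures, built in code.

# A compact noisy design: quick to simulate and summarize.
small_config <- function(seed = 1, ...) {
  sim_config(n_genes = 80L, probes_per_gene = 3L, seed = seed, ...)
}

# All stochastic terms off: intensities are exactly abundance x TE.
noiseless_config <- function(seed = 1, ...) {
  sim_config(n_genes = 60L, probes_per_gene = 3L,
             sigma_bio = 0, sigma_tech = 0, sigma_probe = 0, sigma_scale = 0,
             sigma_ct = 0, seed = seed, ...)
}

# Hand-built two-strain, three-project summarized matrix from given TE and
# abundance vectors (one column per strain x fraction x project group).
toy_summarized <- function(te_wt, te_mut, abundance = rep(100, length(te_wt))) {
  n <- length(te_wt)
  sheet <- expand.grid(fraction = c("HP", "T"), project = c("I", "II", "III"),
                       strain = c("WT", "mutant"), stringsAsFactors = FALSE)
  sheet$array_id <- paste(sheet$strain, sheet$fraction, sheet$project, sep = "_")
  m <- sapply(seq_len(nrow(sheet)), function(j) {
    te <- if (sheet$strain[j] == "WT") te_wt else te_mut
    if (sheet$fraction[j] == "HP") abundance * te else abundance
  })
  dimnames(m) <- list(sprintf("g%02d", seq_len(n)), sheet$array_id)
  attr(m, "scale") <- "linear"
  list(matrix = m, sheet = sheet[, c("array_id", "strain", "fraction", "project")])
}
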