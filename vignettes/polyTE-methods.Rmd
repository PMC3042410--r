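---
title: "Methods: translational-efficiency analysis of polysome-profiling arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: translational-efficiency analysis of polysome-profiling arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyTE)
```

## The measurement and the model

Polysome profiling fractionates mRNAs by ribosome load on a sucrose gradient.
Arrays probed with cDNA from the heavy-polysome pool (HP) and from total RNA
(T) yield, per gene, a translational efficiency `TE = I(HP) / I(T)`. Because
each array is normalized to a common average intensity, TEs are *relative*
quantities: they compare genes within a strain, and a given gene's change
between strains, but not absolute ribosome occupancy.

The scientific object of this package is the genome-wide *distribution* of
TEs in two strains. If a perturbation compresses log2 TEs by a factor
$\beta < 1$,

$$\log_2 TE^{mut}_g = \beta \, \log_2 TE^{wt}_g,$$

then three observable signatures follow, each computed by `te_fit()`:

1. the OLS regression of $\log_2 TE^{wt}$ on $\log_2 TE^{mut}$ has slope
   $1/\beta > 1$;
2. the variance of the MA log-ratio $M = \log_2 I(HP) - \log_2 I(T)$ is
   $\approx \beta^2$-fold smaller in the mutant;
3. fewer mutant genes lie beyond fixed TE thresholds (1.5, 2.0, 0.67, 0.5,
   inclusive) in either tail.

Genes responding most are classified by the mean of per-project mutant/WT TE
ratios — at most 0.71 (down) or at least 1.4 (up) — combined with a
two-tailed pooled-variance Student t-test (p ≤ 0.1) of the three mutant
versus three wild-type per-project TEs. Raw p-values are used, matching the
small-replicate, exploratory character of the design; a Benjamini–Hochberg
column is emitted for information only.

## Preprocessing chain and its order

`te_fit()` runs: quantile normalization → log2 → median-polish summarization
→ technical-replicate averaging (linear scale) → TE ratios. Choices worth
stating:

* **Quantile normalization** equalizes the arrays' marginal intensity
  distributions (sorted columns are replaced by the across-array mean of
  sorted values; ties receive the mean of the tied reference values). It is
  *only* the identity map when all columns already share one distribution.
  This matters for validation: on noise-free synthetic data the HP and T
  arrays have genuinely different distributions (HP intensities are abundance
  × TE), so forcing a common distribution would perturb the very ratios being
  validated. The noise-free closure checks therefore run with
  `normalize = "none"` — with unit scale factors and zero noise there is
  nothing to normalize — and recover truth exactly; the noisy, full-chain
  analyses keep quantile normalization on, accepting a small, shared
  distortion as real analyses do. Background correction (the RMA
  normal-exponential convolution) is deliberately omitted: it is a
  scanner-level step delegated to vendor software, and the simulator
  produces background-free intensities.
* **Median polish** fits `log2 I = mu + probe + array + residual` by
  alternating row/column median sweeps (midpoint rule for even counts),
  stopping when the sum of absolute residuals changes by a relative factor
  below `tol = 1e-6` or after `max_iter = 20` sweeps — the conventional
  settings. The per-array summary is `mu + array effect`. The iteration is
  implemented in C++ (a direct port of the classic algorithm, verified
  against `stats::medpolish` in the test suite) because genome-scale data
  mean thousands of small polish fits per run.
* **Technical replicates** are averaged on the *linear* scale before ratios
  are taken, because TE is defined as a ratio of intensity values, which are
  linear-scale summaries. `summarize_tech_reps(space = "log2")` exposes the
  alternative, since scanner pipelines differ on this point.
* **Pooled TEs** (one value per strain per gene) default to the
  ratio-of-means over all nine arrays' worth of data
  (`pooled = "ratio_of_means"`), consistent with computing one TE from all
  measurements; mean-of-ratios is switchable. Per-project ratios, their SEM,
  and the t-test always use the per-project TEs.
* **Regression orientation**: wild type is the response, mutant the
  predictor, so range narrowing appears as a slope above 1; `te_regression()`
  accepts `response = "mut"` for the transposed convention.
* **Degenerate t-tests** (both triples zero-variance) are defined as p = 0
  when the means differ and p = 1 when equal, and flagged, so classification
  is total on pathological inputs.
* **"Genome average" TE** is the arithmetic mean of pooled mean TEs over all
  genes, used both for the above/below-average strata of
  `group_mean_ratio()` and for context in summaries.

For the low-TE dependency stratum (`dependency_fractions()`), both
directions of the strict comparison are reported (`low_frac_wt_gt` and
`low_frac_wt_lt`): genes with low wild-type TE that are "translated less
efficiently in wild type" satisfy TE_wt < TE_mut, but the complementary
convention appears in the field's tabulations, so neither is privileged.

## The synthetic-data generator

`sim_config()` defaults encode the emulated study: 6000 genes (≈ the ~5900
ORFs of a yeast whole-genome array), 4 probes per gene, 3 biological
projects × 3 technical replicate arrays, strains WT and mutant, fractions HP
and T (LP behind `with_lp = TRUE`), and $\beta = 1/1.30 \approx 0.77$, the
compression implied by a narrowing regression slope of 1.30.

True log2 TEs are Gaussian (`sigma_te = 0.55`) plus a negative coupling
(−0.20) to centred log2 ORF length — short-ORF mRNAs are better translated —
then centred so the genome-mean log2 TE is exactly 0 (the consequence of
equal-average array scaling). The mutant column is exactly
$\beta \times$ the wild-type column. Abundances are log-normal
(log2 N(8, 1.2)). Expected linear intensities are abundance (T arrays) or
abundance × TE (polysomal arrays); LP arrays, when enabled, use the same
underlying TE as HP — a simplification, since real LP/T ratios would reflect
partial ribosome loading.

Noise is log-normal (additive in log2) at three levels, with one global
scale offset per array:

| parameter | default | acts per | emulates |
|---|---|---|---|
| `sigma_bio` | 0.10 | gene × RNA sample | culture + fractionation variability |
| `sigma_tech` | 0.10 | probe × array | hybridization/scanning noise |
| `sigma_probe` | 0.25 | probe (fixed) | sequence-dependent affinity |
| `sigma_scale` | 0.05 | array | loading/labeling scale |

No noise magnitudes are published for this design, so these were fixed once
by a variance budget: they put the MA variance between biological replicates
of the same strain near 0.02–0.03 (the "low" replicate variances typical of
such data) while the HP:T MA variance is dominated by the true TE spread
(≈ 0.33 in WT), giving the WT:mutant variance contrast of ≈ 1.5–1.7 — which
cannot exceed $1/\beta^2 = 1.69$ under pure compression, so the published
"~2-fold" contrast is reproduced as closely as the model admits. With these
defaults the attenuated fitted slope is ≈ 1.21 against the noise-free 1.30,
and the simulated genome-mean TEs (≈ 1.08 WT, ≈ 1.05 mutant) fall where
right-skewed TE distributions with these spreads place them.

Feature distributions target published genome-wide statistics: 5'UTR lengths
log-normal with mean 89 nt, uORF counts Poisson(0.36), ORF lengths
log-normal around 1.2–1.4 kb, 18% essential genes, a 0.5% strong-structure
(MFE) flag, and ribosome densities centred on 0.64 per 100 nt with a
negative ORF-length exponent. uORF counts are drawn independently of 5'UTR
length — a known simplification (long UTRs accumulate more uORFs in real
genomes).

Determinism: every generator stage seeds its own sub-stream derived from
`config$seed`, so identical configurations are byte-identical and stages are
individually reproducible.

**What passing tests do and do not show.** The generator realizes the
compression model exactly, with symmetric log-normal noise and no
background, saturation, cross-hybridization, batch structure, or
mRNA-turnover coupling. Recovery of β here validates the estimator chain,
not the biology of any real dataset; on real arrays the slope additionally
absorbs normalization bias and intensity-dependent noise.

## qPCR quantification

Relative abundance of a transcript in a gradient pool is
$2^{-\Delta\Delta C_t}$ with
$\Delta\Delta C_t = (C_t^{frac,GOI} - C_t^{frac,18S}) -
(C_t^{tot,GOI} - C_t^{tot,18S})$, assuming perfect per-cycle doubling
(no efficiency correction). Replicate Cts are averaged in cycle space (the
geometric mean of quantities); quantity-space averaging is available and the
test suite pins the case where they differ. Pool quantities are multiplied
by the strain's A280 gradient weights — shipped defaults: WT
0.416/0.276/0.308 and mutant 0.738/0.149/0.114 (Mono/LP/HP; the mutant set
sums to 1.001 as measured and is used without renormalization) — and
normalized to proportions. The TE-ratio validation formula multiplies the
strains' $2^{-\Delta\Delta C_t(HP-T)}$ ratio by the HP weight ratio
0.114/0.308, so equal Cts reduce to 0.370. `simulate_ct_table()` inverts
this arithmetic exactly, which the round-trip tests exploit.

## Numerical and testing choices

Problem sizes were chosen so the default suite exercises genome scale
without waste: law-of-large-numbers checks on feature distributions use 6000
genes; end-to-end recovery uses five replicate simulations of the full
6000-gene design; oracle-equivalence checks (quantile normalization vs a
hand sort/average oracle and limma, median polish vs `stats::medpolish`,
pooled t vs `stats::t.test`, Fisher p vs exhaustive hypergeometric
enumeration, OLS vs the closed-form covariance ratio) run on small random
instances where the oracles are exact. Invariants — determinism,
threshold-count nesting, classification monotonicity, ΔΔCt shift
invariance, probability-vector outputs — are checked property-style over
batches of random cases under fixed seeds.

## Limitations

* Array-era ratio analysis: no count models, no moderated variance
  shrinkage; per-gene inference rests on three biological replicates.
* TEs are relative; genome-wide normalization absorbs global shifts in
  polysome content, so absolute translation-rate changes are invisible.
* RMA background correction and probe-sequence effects are out of scope.
* Functional-category enrichment expects a user-supplied annotation; no
  ontology service is consulted.
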