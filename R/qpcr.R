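#' A280 gradient fraction weights
#'
#' The proportion of total gradient A280 absorbance found in the monosome
#' (Mono), light-polysome (LP) and heavy-polysome (HP) pools, per strain.
#' The packaged default is the measured set for the wild-type and
#' eIF4G-depleted mutant gradients: WT 0.416/0.276/0.308 and mutant
#' 0.738/0.149/0.114 (Mono/LP/HP). The mutant proportions sum to 1.001 as
#' printed and are used without renormalization.
#'
#' @return A list of class `"a280_weights"` mapping strain to a named
#'   numeric vector over `Mono`, `LP`, `HP`.
#' @export
a280_weights <- function() {
  structure(list(
    WT = c(Mono = 0.416, LP = 0.276, HP = 0.308),
    mutant = c(Mono = 0.738, LP = 0.149, HP = 0.114)
  ), class = "a280_weights")
}

.strain_weights <- function(weights, strain) {
  w <- weights[[strain]]
  if (is.null(w))
    stop("data error: no fraction weights for strain '", strain, "'",
         call. = FALSE)
  if (any(w <= 0) || any(w > 1) || abs(sum(w) - 1) > 0.01)
    stop("data error: fraction weights must be in (0,1] and sum to 1 (+-0.01)",
         call. = FALSE)
  w
}

#' Relative quantity by the 2^-ddCt method
#'
#' Computes `2^-ddCt` with `ddCt = (Ct_goi_fraction - Ct_ref_fraction) -
#' (Ct_goi_total - Ct_ref_total)`: the abundance of the gene of interest in
#' a gradient fraction relative to total RNA, normalized to the reference
#' transcript (18S rRNA). Assumes perfect per-cycle doubling. Vectorised.
#'
#' @param ct_goi_frac,ct_ref_frac Cts of the gene of interest and the
#'   reference in the fraction.
#' @param ct_goi_total,ct_ref_total The corresponding Cts in total RNA.
#' @return The relative quantity `2^-ddCt`.
#' @examples
#' delta_delta_ct(20, 10, 22, 10)  # 4: two cycles earlier than total
#' @export
delta_delta_ct <- function(ct_goi_frac, ct_ref_frac, ct_goi_total, ct_ref_total) {
  ddct <- (ct_goi_frac - ct_ref_frac) - (ct_goi_total - ct_ref_total)
  2^(-ddct)
}

#' Average replicate Ct values
#'
#' Technical qPCR replicates are averaged in Ct (cycle) space by default,
#' i.e. the arithmetic mean of cycles, which is the geometric mean of
#' quantities; `space = "quantity"` instead averages `2^-Ct` and converts
#' back.
#'
#' @param ct Numeric vector of replicate Ct values.
#' @param space `"ct"` (default) or `"quantity"`.
#' @return The averaged Ct (a single cycle value).
#' @export
average_ct <- function(ct, space = c("ct", "quantity")) {
  space <- match.arg(space)
  if (space == "ct") mean(ct) else -log2(mean(2^-ct))
}

#' Polysome distribution from per-fraction relative quantities
#'
#' Multiplies each fraction's `2^-ddCt` relative quantity by the proportion
#' of total gradient A280 in that fraction pool and normalizes, giving the
#' proportion of the transcript's gradient-wide signal in each of the Mono,
#' LP and HP pools (summing to exactly 1).
#'
#' @param quantities Named numeric vector of relative quantities with
#'   entries `Mono`, `LP`, `HP`.
#' @param weights An [a280_weights()] set (or compatible list).
#' @param strain Strain whose weight set applies.
#' @return Named proportion vector over `Mono`, `LP`, `HP`.
#' @export
polysome_distribution <- function(quantities, weights = a280_weights(),
                                  strain = "WT") {
  need <- c("Mono", "LP", "HP")
  if (!all(need %in% names(quantities)))
    stop("data error: quantities required for fractions ",
         paste(setdiff(need, names(quantities)), collapse = ", "), call. = FALSE)
  q <- quantities[need]
  if (any(!is.finite(q)) || any(q <= 0))
    stop("data error: quantities must be positive", call. = FALSE)
  w <- .strain_weights(weights, strain)
  v <- q * w[need]
  v / sum(v)
}

#' qPCR estimate of the mutant/wild-type TE ratio
#'
#' The validation formula for array-derived TE ratios: the strain-wise
#' `2^-ddCt(HP - T)` values are divided (mutant over wild type) and
#' multiplied by the ratio of the strains' HP A280 weights
#' (0.114/0.308 for the packaged default set), converting the
#' within-gradient relative quantities to gradient-wide HP proportions.
#'
#' @param mut_hp,mut_t,wt_hp,wt_t Named numeric vectors `c(goi = , ref = )`
#'   with the (replicate-averaged) Cts of the gene of interest and the 18S
#'   reference in the HP fraction and total RNA of each strain.
#' @param weights An [a280_weights()] set.
#' @return The estimated TE_mut/TE_wt ratio.
#' @examples
#' ct <- c(goi = 25, ref = 15)
#' qpcr_te_ratio(ct, ct, ct, ct)  # weight-only identity: 0.114/0.308
#' @export
qpcr_te_ratio <- function(mut_hp, mut_t, wt_hp, wt_t,
                          weights = a280_weights()) {
  pick <- function(v, nm) {
    if (!all(c("goi", "ref") %in% names(v)))
      stop("data error: ", nm, " must name goi and ref Cts", call. = FALSE)
    v
  }
  mut_hp <- pick(mut_hp, "mut_hp"); mut_t <- pick(mut_t, "mut_t")
  wt_hp <- pick(wt_hp, "wt_hp"); wt_t <- pick(wt_t, "wt_t")
  q_mut <- delta_delta_ct(mut_hp[["goi"]], mut_hp[["ref"]],
                          mut_t[["goi"]], mut_t[["ref"]])
  q_wt <- delta_delta_ct(wt_hp[["goi"]], wt_hp[["ref"]],
                         wt_t[["goi"]], wt_t[["ref"]])
  w_mut <- .strain_weights(weights, "mutant")[["HP"]]
  w_wt <- .strain_weights(weights, "WT")[["HP"]]
  (q_mut / q_wt) * (w_mut / w_wt)
}

#' Polysome distributions from a Ct table
#'
#' End-to-end quantification: averages technical replicate Cts (Ct space by
#' default), computes each fraction's `2^-ddCt` relative to total RNA, and
#' applies [polysome_distribution()], per gene and strain.
#'
#' @param ct_table Ct table with columns `gene_id`, `strain`, `fraction`
#'   (`Mono`/`LP`/`HP`/`Total`), `target` (`GOI`/`18S`), `replicate`, `ct`,
#'   e.g. from [simulate_ct_table()] or [read_ct()].
#' @param weights An [a280_weights()] set.
#' @param space Replicate-averaging space, see [average_ct()].
#' @return A `data.frame`: `gene_id`, `strain`, `Mono`, `LP`, `HP` (each
#'   row's proportions sum to 1).
#' @export
polysome_profile <- function(ct_table, weights = a280_weights(),
                             space = c("ct", "quantity")) {
  space <- match.arg(space)
  need <- c("gene_id", "strain", "fraction", "target", "ct")
  miss <- setdiff(need, names(ct_table))
  if (length(miss))
    stop("data error: Ct table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  groups <- unique(ct_table[c("gene_id", "strain")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- ct_table[ct_table$gene_id == groups$gene_id[i] &
                    ct_table$strain == groups$strain[i], ]
    ct_of <- function(fraction, target) {
      v <- g$ct[g$fraction == fraction & g$target == target]
      if (length(v) == 0L)
        stop("data error: missing Cts for ", fraction, "/", target, " of gene ",
             groups$gene_id[i], call. = FALSE)
      average_ct(v, space = space)
    }
    tot_goi <- ct_of("Total", "GOI"); tot_ref <- ct_of("Total", "18S")
    q <- vapply(c("Mono", "LP", "HP"), function(f)
      delta_delta_ct(ct_of(f, "GOI"), ct_of(f, "18S"), tot_goi, tot_ref),
      numeric(1))
    pr <- polysome_distribution(q, weights, groups$strain[i])
    data.frame(gene_id = groups$gene_id[i], strain = groups$strain[i],
               Mono = pr[["Mono"]], LP = pr[["LP"]], HP = pr[["HP"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
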