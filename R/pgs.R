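#' Build clumping-and-thresholding polygenic score weights
#'
#' Clumps one trait's summary statistics on the reference panel's LD
#' (greedy, index = smallest p, members within `kb` kilobases at r-squared
#' above `r2`, entry at `p < p1`), keeps lead variants with `p < score_p`,
#' and returns their scan betas oriented to the effect (alternate) allele.
#' Variants absent from the reference panel, or with mismatched alleles, are
#' dropped with a report.
#'
#' @param sumstats scan results for a single trait (columns variant, chrom,
#'   pos, beta, p).
#' @param ref_geno reference `genotype_matrix` for LD.
#' @param p1 clump entry threshold (default 0.5).
#' @param r2 clump r-squared (default 0.5).
#' @param kb clump distance in kb (default 100).
#' @param score_p p-value threshold for the scoring step (default 0.1).
#' @return data.frame (variant, effect_allele, weight, trait) of class
#'   `pgs_weights`, with the dropped-variant report attached as attribute
#'   `"dropped"`.
#' @export
build_pgs <- function(sumstats, ref_geno, p1 = 0.5, r2 = 0.5, kb = 100,
                      score_p = 0.1) {
  stopifnot(length(unique(sumstats$trait)) <= 1L)
  v <- ref_geno$variants
  hit <- match(sumstats$variant, v$id)
  dropped <- sumstats$variant[is.na(hit)]
  ss <- sumstats[!is.na(hit), , drop = FALSE]
  ss <- ss[!is.na(ss$p), , drop = FALSE]

  cfg <- scan_config(sig_threshold = p1, clump_r2 = r2, clump_kb = kb,
                     min_traits = 1L)
  regions <- clump(ss, ref_geno, cfg)
  leads <- vapply(regions, `[[`, "", "lead")
  lead_p <- vapply(regions, `[[`, 1.0, "lead_p")
  keep <- leads[lead_p < score_p]
  if (!length(keep))
    warning("build_pgs: no variants pass the scoring threshold")
  sel <- ss[match(keep, ss$variant), , drop = FALSE]
  out <- data.frame(variant = sel$variant,
                    effect_allele = v$alt[match(sel$variant, v$id)],
                    weight = sel$beta,
                    trait = if (nrow(sel)) sel$trait else character(0),
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  attr(out, "params") <- c(p1 = p1, r2 = r2, kb = kb, score_p = score_p)
  class(out) <- c("pgs_weights", "data.frame")
  out
}

#' Apply polygenic score weights to a cohort
#'
#' `score = sum(weight * dosage)` over the overlapping variants, with the
#' dosage flipped (`2 - dosage`) when the effect allele is the panel's
#' reference allele, and missing dosages imputed to twice the
#' effect-allele frequency of the scoring cohort. Scores are also returned
#' z-scaled within the cohort.
#'
#' @param geno `genotype_matrix` of the scoring cohort.
#' @param weights a `pgs_weights` (or compatible data.frame).
#' @return data.frame (donor, score, score_scaled).
#' @export
score_genotypes <- function(geno, weights) {
  v <- geno$variants
  hit <- match(weights$variant, v$id)
  ok <- !is.na(hit)
  if (!any(ok)) stop_config("score_genotypes: no overlapping variants")
  w <- weights[ok, , drop = FALSE]
  idx <- hit[ok]
  flip <- w$effect_allele == v$ref[idx]
  mismatch <- !flip & w$effect_allele != v$alt[idx]
  if (any(mismatch)) {
    w <- w[!mismatch, , drop = FALSE]
    idx <- idx[!mismatch]
    flip <- flip[!mismatch]
    if (!nrow(w)) stop_config("score_genotypes: no allele-consistent variants")
  }
  g <- geno$dosage[, idx, drop = FALSE]
  if (any(flip)) g[, flip] <- 2 - g[, flip]
  eaf <- colMeans(g, na.rm = TRUE) / 2
  if (any(!is.finite(eaf))) {
    # variant unobserved in the scoring cohort: fall back to the panel's
    # target frequency when present, else 0.5
    fallback <- v$maf_target[idx]
    fallback[!is.finite(fallback)] <- 0.5
    fallback <- ifelse(flip, 1 - fallback, fallback)
    eaf[!is.finite(eaf)] <- fallback[!is.finite(eaf)]
  }
  for (j in seq_len(ncol(g))) {
    nas <- is.na(g[, j])
    if (any(nas)) g[nas, j] <- 2 * eaf[j]
  }
  raw <- as.numeric(g %*% w$weight)
  scaled <- if (stats::sd(raw) > 0) as.numeric(scale(raw)) else raw * 0
  data.frame(donor = geno$donors, score = raw, score_scaled = scaled,
             stringsAsFactors = FALSE)
}
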