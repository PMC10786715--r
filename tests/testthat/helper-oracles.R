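# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Exact HWE p by full enumeration of heterozygote counts (feasible for
# total <= 10): conditional probability of n_Aa heterozygotes given allele
# counts is C(n; nAA, nAa, naa) 2^nAa / C(2n, n_rare).
hwe_enumeration_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  rare <- 2 * min(n_AA, n_aa) + n_Aa
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  pr <- vapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    exp(lfactorial(n) - lfactorial(h) - lfactorial(hom_r) - lfactorial(hom_c) +
          h * log(2) - (lchoose(2 * n, rare)))
  }, numeric(1))
  p_obs <- pr[match(n_Aa, hets)]
  sum(pr[pr <= p_obs * (1 + 1e-12)])
}

# Exhaustive greedy clumping oracle: plain double loops, no vectorization
# shared with the implementation.
clump_oracle <- function(results, dosage, variants, sig = 5e-8, r2 = 0.5,
                         kb = 250, min_traits = 2) {
  s <- results[!is.na(results$p) & results$p < sig, , drop = FALSE]
  if (!nrow(s)) return(list())
  vb <- list()
  for (v in unique(s$variant)) {
    d <- s[s$variant == v, ]
    vb[[v]] <- list(p = min(d$p),
                    pos = variants$pos[match(v, variants$id)],
                    chrom = variants$chrom[match(v, variants$id)])
  }
  left <- names(vb)
  regions <- list()
  while (length(left)) {
    ps <- vapply(left, function(v) vb[[v]]$p, numeric(1))
    pos <- vapply(left, function(v) vb[[v]]$pos, numeric(1))
    ord <- order(ps, pos)
    index <- left[ord[1]]
    members <- index
    for (v in setdiff(left, index)) {
      if (vb[[v]]$chrom != vb[[index]]$chrom) next
      if (abs(vb[[v]]$pos - vb[[index]]$pos) >= kb * 1000) next
      r <- suppressWarnings(stats::cor(dosage[, index], dosage[, v],
                                       use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 > r2) members <- c(members, v)
    }
    left <- setdiff(left, members)
    msig <- s[s$variant %in% members, ]
    regions[[length(regions) + 1L]] <- list(
      members = sort(members),
      traits = sort(unique(msig$trait)),
      lead = msig$variant[which.min(msig$p)])
  }
  Filter(function(r) length(r$traits) >= min_traits, regions)
}

# Minimal genotype_matrix construction for ad-hoc dosage matrices.
make_geno <- function(dosage, pos = NULL, chrom = "1") {
  m <- ncol(dosage)
  rownames(dosage) <- sprintf("d%03d", seq_len(nrow(dosage)))
  colnames(dosage) <- sprintf("v%03d", seq_len(m))
  structure(list(
    dosage = dosage,
    variants = data.frame(chrom = chrom, pos = pos %||% (seq_len(m) * 1000L),
                          id = colnames(dosage), ref = "A", alt = "G",
                          maf_target = colMeans(dosage, na.rm = TRUE) / 2,
                          stringsAsFactors = FALSE),
    donors = rownames(dosage)), class = "genotype_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_sim_config <- function(...) {
  simulation_config(n_donors = 40L, n_variants = 60L,
                    events_per_sample = 300L, ...)
}
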