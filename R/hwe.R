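#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact two-sided p-value conditional on the observed allele counts: the sum
#' of probabilities of all heterozygote counts whose conditional probability
#' does not exceed that of the observed count. Probabilities follow the
#' standard recurrence over heterozygote counts (evaluated outward from the
#' distribution mode, so extreme configurations stay numerically
#' representable). Monomorphic sites return p = 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total >= 1).
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1L) stop_config("hwe_exact_test: total count must be >= 1")
  rare <- 2 * min(n_AA, n_aa) + n_Aa     # copies of the rarer allele
  if (rare == 0) return(1)

  # possible heterozygote counts share the parity of the rare-allele count
  het_vals <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  probs <- numeric(length(het_vals))

  # distribution mode of the het count
  mode_het <- round(rare * (2 * n - rare) / (2 * n - 1))
  if (mode_het %% 2 != rare %% 2) mode_het <- mode_het + 1
  mode_het <- min(max(mode_het, het_vals[1]), het_vals[length(het_vals)])
  i_mode <- match(mode_het, het_vals)

  # unnormalized probabilities via the het-count recurrence:
  # P(h+2)/P(h) = [ (rare-h)/2 * ((2n-rare-h)/2) * 4 ] / [ (h+2)(h+1) ]
  probs[i_mode] <- 1
  if (i_mode < length(het_vals)) {
    for (i in (i_mode + 1):length(het_vals)) {
      h <- het_vals[i - 1]
      hom_r <- (rare - h) / 2
      hom_c <- n - h - hom_r
      probs[i] <- probs[i - 1] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
    }
  }
  if (i_mode > 1) {
    for (i in (i_mode - 1):1) {
      h <- het_vals[i + 1]
      hom_r <- (rare - h) / 2
      hom_c <- n - h - hom_r
      probs[i] <- probs[i + 1] * h * (h - 1) / (4 * (hom_r + 1) * (hom_c + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_Aa, het_vals)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}
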