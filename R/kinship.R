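#' KING-robust kinship for a pair of individuals
#'
#' Computes `phi = (N_Aa,Aa - 2 * N_AA,aa) / (N_Aa(i) + N_Aa(j))` over
#' jointly observed hard-called genotypes, where the terms count
#' double-heterozygote sites, opposite-homozygote sites, and heterozygous
#' sites per individual. Dosages are hard-called at thresholds 0.5 and 1.5.
#' Expected values: 0.5 for duplicates/MZ twins, 0.25 for first-degree
#' relatives, ~0 for unrelateds.
#'
#' @param dosages_i,dosages_j numeric dosage vectors in `[0, 2]` (NA allowed).
#' @return kinship estimate phi (NA with a warning when the denominator is
#'   zero).
#' @export
king_kinship <- function(dosages_i, dosages_j) {
  stopifnot(length(dosages_i) == length(dosages_j))
  gi <- hard_call(dosages_i)
  gj <- hard_call(dosages_j)
  ok <- !is.na(gi) & !is.na(gj)
  if (sum(ok) < 100L)
    warning(sprintf("king_kinship: only %d jointly observed sites", sum(ok)))
  gi <- gi[ok]; gj <- gj[ok]
  het_i <- sum(gi == 1L)
  het_j <- sum(gj == 1L)
  if (het_i + het_j == 0) {
    warning("king_kinship: no heterozygous sites in either individual")
    return(NA_real_)
  }
  n_hethet <- sum(gi == 1L & gj == 1L)
  n_opp <- sum((gi == 0L & gj == 2L) | (gi == 2L & gj == 0L))
  (n_hethet - 2 * n_opp) / (het_i + het_j)
}

hard_call <- function(dosage) {
  g <- rep(NA_integer_, length(dosage))
  ok <- !is.na(dosage)
  g[ok] <- ifelse(dosage[ok] < 0.5, 0L, ifelse(dosage[ok] > 1.5, 2L, 1L))
  g
}

# All pairwise KING estimates via cross-products (used by variant_qc's
# relatedness pruning). Returns a data.frame of pairs with phi.
king_kinship_pairs <- function(dosage) {
  g <- apply(dosage, 2L, hard_call)
  obs <- !is.na(g)
  h <- (g == 1L) & obs
  a0 <- (g == 0L) & obs
  a2 <- (g == 2L) & obs
  h[!obs] <- FALSE; a0[!obs] <- FALSE; a2[!obs] <- FALSE
  n_hethet <- tcrossprod(h * 1)
  n_opp <- tcrossprod(a0 * 1, a2 * 1)
  n_opp <- n_opp + t(n_opp)
  het_i <- tcrossprod(h * 1, obs * 1)   # het sites of i jointly observed with j
  denom <- het_i + t(het_i)
  phi <- (n_hethet - 2 * n_opp) / denom
  idx <- which(upper.tri(phi), arr.ind = TRUE)
  data.frame(i = rownames(dosage)[idx[, 1]], j = rownames(dosage)[idx[, 2]],
             phi = phi[idx], stringsAsFactors = FALSE)
}
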