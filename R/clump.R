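#' Greedy LD clumping with a multi-trait support rule
#'
#' Associations with `p < sig_threshold` enter. Repeatedly the unassigned
#' significant variant with the smallest p across all traits (ties broken by
#' smaller position, then chromosome) becomes an index; every unassigned
#' significant variant on the same chromosome within `clump_kb` kilobases and
#' with genotype r-squared above `clump_r2` to the index joins its region.
#' Regions supported by fewer than `min_traits` independent hits are then
#' discarded -- "independent" meaning distinct trait names
#' (`support = "traits"`) or distinct member variants (`support =
#' "variants"`). The lead variant is the member with the smallest
#' association p across all traits.
#'
#' @param results scan results (rbind of [association_scan()] across traits).
#' @param geno the `genotype_matrix` used for LD (dosage correlation,
#'   pairwise-complete).
#' @param config a [scan_config()].
#' @return list of regions; each has `lead`, `lead_p`, `members`,
#'   `supporting_traits`, `chrom`, `span`. An empty list when nothing is
#'   significant.
#' @export
clump <- function(results, geno, config = scan_config()) {
  sig <- results[!is.na(results$p) & results$p < config$sig_threshold, ,
                 drop = FALSE]
  if (!nrow(sig)) return(list())

  # per-variant best association
  best <- do.call(rbind, lapply(split(sig, sig$variant), function(d) {
    d[which.min(d$p), c("variant", "chrom", "pos", "p"), drop = FALSE]
  }))
  best <- best[order(best$p, best$pos, best$chrom), , drop = FALSE]

  dose <- geno$dosage[, intersect(colnames(geno$dosage), best$variant),
                      drop = FALSE]
  unassigned <- stats::setNames(rep(TRUE, nrow(best)), best$variant)
  regions <- list()
  while (any(unassigned)) {
    cand <- best[unassigned[best$variant], , drop = FALSE]
    idx <- cand[1, ]
    members <- idx$variant
    others <- cand$variant[-1]
    if (length(others)) {
      same_chr <- cand$chrom[-1] == idx$chrom
      close <- abs(cand$pos[-1] - idx$pos) < config$clump_kb * 1000
      pool <- others[same_chr & close]
      if (length(pool)) {
        r <- suppressWarnings(stats::cor(dose[, idx$variant], dose[, pool],
                                         use = "pairwise.complete.obs"))
        r2 <- as.numeric(r)^2
        members <- c(members, pool[!is.na(r2) & r2 > config$clump_r2])
      }
    }
    unassigned[members] <- FALSE
    msig <- sig[sig$variant %in% members, , drop = FALSE]
    support <- if (config$support == "traits") unique(msig$trait)
               else unique(msig$variant)
    lead_row <- msig[which.min(msig$p), ]
    regions[[length(regions) + 1L]] <- list(
      lead = lead_row$variant, lead_p = lead_row$p,
      lead_trait = lead_row$trait, members = members,
      supporting_traits = sort(unique(msig$trait)),
      n_support = length(support), chrom = idx$chrom,
      span = range(best$pos[best$variant %in% members]))
  }
  Filter(function(r) r$n_support >= config$min_traits, regions)
}

#' Summarize clumped regions as a table
#'
#' @param regions output of [clump()].
#' @return data.frame, one row per region.
#' @export
clump_table <- function(regions) {
  if (!length(regions))
    return(data.frame(lead = character(), lead_trait = character(),
                      lead_p = numeric(), chrom = character(),
                      span_start = integer(), span_end = integer(),
                      n_members = integer(), supporting_traits = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(regions, function(r) data.frame(
    lead = r$lead, lead_trait = r$lead_trait, lead_p = r$lead_p,
    chrom = r$chrom, span_start = r$span[1], span_end = r$span[2],
    n_members = length(r$members),
    supporting_traits = paste(r$supporting_traits, collapse = ","),
    stringsAsFactors = FALSE)))
}

#' Select top traits per clumped region
#'
#' For each region, the `k` traits with the smallest association p among the
#' region's member variants; the union over regions is returned
#' de-duplicated (first-occurrence order by significance).
#'
#' @param results scan results across traits.
#' @param regions output of [clump()].
#' @param k traits per region (default 3).
#' @export
select_top_traits <- function(results, regions, k = 3) {
  picked <- character(0)
  for (r in regions) {
    m <- results[results$variant %in% r$members & !is.na(results$p), ,
                 drop = FALSE]
    m <- m[order(m$p), , drop = FALSE]
    traits <- unique(m$trait)
    picked <- c(picked, utils::head(traits, k))
  }
  unique(picked)
}
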