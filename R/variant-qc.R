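#' Scan configuration
#'
#' Thresholds for variant/sample QC, the association scan and LD clumping.
#' Defaults follow standard biobank-scale practice: MAF floor 0.05, MAC
#' floor 10, variant missingness ceiling 0.10, Hardy-Weinberg p floor 1e-50,
#' KING kinship ceiling 0.177 (first-degree), genome-wide significance 5e-8,
#' clump r-squared 0.50 within 250 kb, and at least two distinct supporting
#' traits per clumped region.
#'
#' @param maf_floor,mac_floor,miss_ceiling,hwe_floor variant thresholds.
#' @param sample_miss_ceiling per-donor missingness ceiling.
#' @param kinship_ceiling KING phi above which one member of a pair is
#'   dropped (the one with higher missingness).
#' @param sig_threshold genome-wide significance level for clumping entry.
#' @param clump_r2,clump_kb clumping LD and distance bounds.
#' @param min_traits minimum distinct supporting traits per region.
#' @param support "traits" (distinct trait names) or "variants" (distinct
#'   member variants with significant hits).
#' @export
scan_config <- function(maf_floor = 0.05, mac_floor = 10, miss_ceiling = 0.10,
                        hwe_floor = 1e-50, sample_miss_ceiling = 0.10,
                        kinship_ceiling = 0.177, sig_threshold = 5e-8,
                        clump_r2 = 0.50, clump_kb = 250, min_traits = 2L,
                        support = c("traits", "variants")) {
  support <- match.arg(support)
  stopifnot(maf_floor >= 0, maf_floor <= 0.5, miss_ceiling >= 0,
            miss_ceiling <= 1, hwe_floor >= 0, hwe_floor <= 1,
            clump_r2 >= 0, clump_r2 <= 1, clump_kb > 0, min_traits >= 1)
  structure(list(maf_floor = maf_floor, mac_floor = mac_floor,
                 miss_ceiling = miss_ceiling, hwe_floor = hwe_floor,
                 sample_miss_ceiling = sample_miss_ceiling,
                 kinship_ceiling = kinship_ceiling,
                 sig_threshold = sig_threshold, clump_r2 = clump_r2,
                 clump_kb = clump_kb, min_traits = as.integer(min_traits),
                 support = support),
            class = "scan_config")
}

#' Variant and sample quality control
#'
#' Drops variants failing missingness, Hardy-Weinberg (exact test on hard
#' calls), MAF or MAC thresholds; drops donors failing sample missingness;
#' optionally prunes related pairs (KING phi above the ceiling; the member
#' with higher missingness is removed). Every exclusion appears exactly once
#' in the report with its reason and offending value.
#'
#' @param geno a `genotype_matrix`.
#' @param config a [scan_config()].
#' @param prune_related run the pairwise KING pruning (quadratic in donors).
#' @return list: `geno` (filtered), `report` (data.frame type, id, reason,
#'   value).
#' @export
variant_qc <- function(geno, config = scan_config(), prune_related = TRUE) {
  g <- geno$dosage
  report <- list()
  add <- function(type, id, reason, value) {
    report[[length(report) + 1L]] <<- data.frame(
      type = type, id = id, reason = reason, value = value,
      stringsAsFactors = FALSE)
  }

  smiss <- rowMeans(is.na(g))
  bad_donor <- smiss > config$sample_miss_ceiling
  for (i in which(bad_donor)) add("donor", rownames(g)[i], "missingness", smiss[i])

  if (prune_related && ncol(g) < 100L) {
    warning("variant_qc: fewer than 100 variants; kinship pruning skipped (KING needs >= 100 sites)")
    prune_related <- FALSE
  }
  if (prune_related && nrow(g) >= 2L) {
    pairs <- king_kinship_pairs(g[!bad_donor, , drop = FALSE])
    flagged <- pairs[!is.na(pairs$phi) & pairs$phi > config$kinship_ceiling, ,
                     drop = FALSE]
    if (nrow(flagged)) {
      miss_of <- stats::setNames(smiss, rownames(g))
      kin_drop <- character(0)
      for (r in seq_len(nrow(flagged))) {
        if (flagged$i[r] %in% kin_drop || flagged$j[r] %in% kin_drop) next
        victim <- if (miss_of[flagged$i[r]] >= miss_of[flagged$j[r]])
          flagged$i[r] else flagged$j[r]
        kin_drop <- c(kin_drop, victim)
        add("donor", victim, "kinship", flagged$phi[r])
      }
      bad_donor <- bad_donor | rownames(g) %in% kin_drop
    }
  }
  g <- g[!bad_donor, , drop = FALSE]

  vmiss <- colMeans(is.na(g))
  n <- nrow(g)
  af <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  hc <- apply(g, 2L, hard_call)
  mac <- apply(hc, 2L, function(v) {
    a <- sum(v, na.rm = TRUE)
    min(a, 2 * sum(!is.na(v)) - a)
  })
  hwe_p <- vapply(seq_len(ncol(g)), function(j) {
    v <- hc[, j]
    hwe_exact_test(sum(v == 0L, na.rm = TRUE), sum(v == 1L, na.rm = TRUE),
                   sum(v == 2L, na.rm = TRUE))
  }, numeric(1))

  bad_variant <- rep(FALSE, ncol(g))
  for (j in seq_len(ncol(g))) {
    id <- colnames(g)[j]
    if (vmiss[j] > config$miss_ceiling) {
      add("variant", id, "missingness", vmiss[j]); bad_variant[j] <- TRUE
    } else if (hwe_p[j] < config$hwe_floor) {
      add("variant", id, "hwe", hwe_p[j]); bad_variant[j] <- TRUE
    } else if (is.na(maf[j]) || maf[j] < config$maf_floor) {
      add("variant", id, "maf", maf[j]); bad_variant[j] <- TRUE
    } else if (mac[j] < config$mac_floor) {
      add("variant", id, "mac", mac[j]); bad_variant[j] <- TRUE
    }
  }

  keep_v <- !bad_variant
  out <- structure(list(
    dosage = g[, keep_v, drop = FALSE],
    variants = geno$variants[keep_v, , drop = FALSE],
    donors = rownames(g)), class = "genotype_matrix")
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(type = character(), id = character(), reason = character(),
               value = numeric(), stringsAsFactors = FALSE)
  list(geno = out, report = report)
}
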