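#' Simulate genotypes with LD-block structure under Hardy-Weinberg equilibrium
#'
#' Each variant carries a latent standard-normal liability per haplotype;
#' within an LD block adjacent liabilities follow an AR(1) process with
#' correlation `ld_rho`, and blocks are independent. Each of a donor's two
#' haplotype liabilities is thresholded at the variant's allele frequency
#' (`z > qnorm(1 - maf)` carries the alternate allele), so single-variant
#' genotype frequencies are exactly Hardy-Weinberg at the drawn MAF while
#' adjacent-variant genotype correlation increases monotonically with
#' `ld_rho`.
#'
#' Variants are placed on one chromosome at 10 kb spacing (1-based positions,
#' ascending). Optional missingness is applied completely at random at
#' `missing_rate`.
#'
#' @param config a [simulation_config()].
#' @return object of class `genotype_matrix`: list with `dosage`
#'   (donors x variants, values 0/1/2 or NA), `variants` (data.frame with
#'   chrom, pos, id, ref, alt, maf_target), `donors` (character ids).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_donors
  m <- config$n_variants
  set.seed(child_seed(config$seed, "genotypes"))

  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  thr <- stats::qnorm(1 - maf)

  block <- rep(seq_len(ceiling(m / config$ld_block_size)),
               each = config$ld_block_size)[seq_len(m)]
  rho <- config$ld_rho

  hap <- function() {
    z <- matrix(stats::rnorm(n * m), n, m)
    if (rho > 0 && m > 1L) {
      for (j in 2:m) {
        if (block[j] == block[j - 1L])
          z[, j] <- rho * z[, j - 1L] + sqrt(1 - rho^2) * z[, j]
      }
    }
    z
  }
  a1 <- sweep(hap(), 2L, thr, ">")
  a2 <- sweep(hap(), 2L, thr, ">")
  dosage <- matrix(as.double(a1) + as.double(a2), n, m)

  if (config$missing_rate > 0) {
    miss <- stats::runif(n * m) < config$missing_rate
    dosage[miss] <- NA_real_
  }

  donors <- sprintf("donor_%04d", seq_len(n))
  rownames(dosage) <- donors
  variants <- data.frame(
    chrom = "1",
    pos = seq_len(m) * 10000L,
    id = sprintf("var_%05d", seq_len(m)),
    ref = "A", alt = "G",
    maf_target = maf,
    stringsAsFactors = FALSE
  )
  colnames(dosage) <- variants$id
  structure(list(dosage = dosage, variants = variants, donors = donors),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d donors x %d variants, %.2f%% missing\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Leading genotype principal components
#'
#' SVD of the centred, allele-frequency-standardized dosage matrix (missing
#' dosages mean-imputed for the decomposition only). Used as ancestry
#' covariates in the association scan and survival models.
#'
#' @param geno a `genotype_matrix`.
#' @param k number of components.
#' @return donors x k matrix of scores (columns PC1..PCk).
#' @export
genotype_pcs <- function(geno, k = 10) {
  g <- geno$dosage
  p <- colMeans(g, na.rm = TRUE) / 2
  keep <- is.finite(p) & p > 0 & p < 1
  g <- g[, keep, drop = FALSE]
  p <- p[keep]
  gs <- sweep(g, 2L, 2 * p)
  gs <- sweep(gs, 2L, sqrt(2 * p * (1 - p)), "/")
  gs[is.na(gs)] <- 0
  k <- min(k, dim(gs) - 1L)
  sv <- svd(gs, nu = k, nv = 0)
  pcs <- sv$u %*% diag(sv$d[seq_len(k)], k)
  colnames(pcs) <- paste0("PC", seq_len(k))
  rownames(pcs) <- geno$donors
  pcs
}

#' Write a genotype matrix as a VCF with GT and DS fields
#'
#' Plain-text VCFv4.2; hard genotype calls are derived from dosages at
#' thresholds 0.5/1.5 and the DS field carries the dosage itself. Missing
#' entries are written as `./.:.`.
#'
#' @param geno a `genotype_matrix`.
#' @param path output file path.
#' @export
write_genotypes_vcf <- function(geno, path) {
  v <- geno$variants
  g <- geno$dosage
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$donors), collapse = "\t")
  ), con)
  gt_of <- function(d) {
    out <- rep("./.:.", length(d))
    ok <- !is.na(d)
    hc <- ifelse(d[ok] < 0.5, "0/0", ifelse(d[ok] > 1.5, "1/1", "0/1"))
    out[ok] <- paste0(hc, ":", format(d[ok], trim = TRUE))
    out
  }
  lines <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(v$chrom[i], v$pos[i], v$id[i], v$ref[i], v$alt[i], ".", "PASS",
            ".", "GT:DS", gt_of(g[, i])), collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read a dosage VCF written by [write_genotypes_vcf()]
#'
#' Uses vcfR when available; otherwise falls back to a plain-text parse of
#' the GT:DS layout this package writes.
#'
#' @param path VCF path.
#' @return a `genotype_matrix`.
#' @export
read_genotypes_vcf <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
    dosage <- t(ds)
    variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                           id = fix$ID, ref = fix$REF, alt = fix$ALT,
                           maf_target = NA_real_, stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "##")]
    hdr <- strsplit(body[1], "\t")[[1]]
    donors <- hdr[-(1:9)]
    rows <- strsplit(body[-1], "\t")
    variants <- data.frame(
      chrom = vapply(rows, `[`, "", 1L),
      pos = as.integer(vapply(rows, `[`, "", 2L)),
      id = vapply(rows, `[`, "", 3L),
      ref = vapply(rows, `[`, "", 4L),
      alt = vapply(rows, `[`, "", 5L),
      maf_target = NA_real_, stringsAsFactors = FALSE)
    # vapply over variant rows returns one column per variant: donors x variants
    dosage <- vapply(rows, function(r) {
      suppressWarnings(as.numeric(sub("^[^:]*:", "", r[-(1:9)])))
    }, numeric(length(donors)))
    dosage <- matrix(dosage, nrow = length(donors),
                     dimnames = list(donors, variants$id))
  }
  colnames(dosage) <- variants$id
  structure(list(dosage = dosage, variants = variants,
                 donors = rownames(dosage)),
            class = "genotype_matrix")
}
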