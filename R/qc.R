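#' Univariate MAD outlier mask
#'
#' Flags cells further than `k` median absolute deviations from the column
#' median, with the MAD scaled by the Gaussian consistency constant 1.4826
#' (the `stats::mad()` default), so `k = 4` corresponds to four robust
#' standard deviations. A column whose MAD is zero flags nothing: discrete
#' traits where most values equal the median would otherwise be discarded
#' wholesale.
#'
#' @param column numeric vector (NAs allowed; never flagged).
#' @param k MAD multiplier (default 4).
#' @return logical mask, `TRUE` = removed.
#' @export
mad_outlier_filter <- function(column, k = 4) {
  ok <- !is.na(column)
  if (sum(ok) == 0L) {
    warning("mad_outlier_filter: all-missing column skipped")
    return(rep(FALSE, length(column)))
  }
  if (sum(ok) < 3L)
    warning("mad_outlier_filter: fewer than 3 non-missing values")
  med <- stats::median(column[ok])
  madv <- 1.4826 * stats::median(abs(column[ok] - med))
  out <- rep(FALSE, length(column))
  if (madv > 0) out[ok] <- abs(column[ok] - med) > k * madv
  out
}

#' Sample-level outlier filter on a 2-D ICA projection
#'
#' Projects the donors of one fluorophore-channel x condition block onto two
#' independent components (missing cells imputed to the column median and
#' columns standardized for the projection only), computes each donor's
#' Euclidean distance to the componentwise median sample, and removes donors
#' whose distance exceeds `median(d) + k * mad(d)` (Gaussian-consistent MAD).
#' If the block has rank below 2 the projection falls back to PCA with a
#' warning. Deterministic for a fixed seed.
#'
#' @param x numeric matrix donors x parameters (>= 10 donors, >= 3
#'   parameters).
#' @param k MAD multiplier (default 2.5).
#' @param seed seed for the ICA initialisation.
#' @return character vector of removed donor ids (rownames of `x`), with the
#'   distance vector attached as attribute `"distance"`.
#' @export
ica_sample_outlier_filter <- function(x, k = 2.5, seed = 1) {
  x <- as.matrix(x)
  if (nrow(x) < 10L || ncol(x) < 3L)
    stop_config("ica_sample_outlier_filter: need >= 10 donors and >= 3 parameters")
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- stats::median(x[, j], na.rm = TRUE)
  }
  sds <- apply(x, 2L, stats::sd)
  keep <- is.finite(sds) & sds > 0
  xs <- scale(x[, keep, drop = FALSE])
  pca_proj <- function(r) {
    p <- stats::prcomp(xs, rank. = min(2L, r))
    cbind(p$x, matrix(0, nrow(xs), 2L - ncol(p$x)))
  }
  r <- qr(sweep(xs, 2L, colMeans(xs)))$rank
  proj <- if (r < 2L) {
    warning("ica_sample_outlier_filter: rank < 2, falling back to PCA")
    pca_proj(r)
  } else {
    # near-Gaussian blocks can defeat the fixed-point iteration; a PCA
    # projection is an acceptable stand-in for the outlier distance
    tryCatch(fast_ica(xs, n_comp = 2, seed = seed)$s,
             error = function(e) {
               warning("ica_sample_outlier_filter: ICA did not converge, falling back to PCA")
               pca_proj(r)
             })
  }
  center <- apply(proj, 2L, stats::median)
  d <- sqrt(rowSums(sweep(proj, 2L, center)^2))
  thr <- stats::median(d) + k * stats::mad(d)
  removed <- rownames(x)[d > thr]
  attr(removed, "distance") <- stats::setNames(d, rownames(x))
  removed
}

#' Rank-based inverse-normal (quantile) transform
#'
#' Value with rank `r` of `n` non-missing values maps to
#' `qnorm((r - 0.5) / n)`; ties receive the average rank; missing values stay
#' missing. A constant column maps to all zeros with a warning.
#'
#' @param column numeric vector.
#' @return numeric vector of normal scores.
#' @export
quantile_transform <- function(column) {
  ok <- !is.na(column)
  n <- sum(ok)
  out <- rep(NA_real_, length(column))
  if (n == 0L) return(out)
  vals <- column[ok]
  if (length(unique(vals)) < 2L) {
    warning("quantile_transform: constant column mapped to 0")
    out[ok] <- 0
    return(out)
  }
  r <- rank(vals, ties.method = "average")
  out[ok] <- stats::qnorm((r - 0.5) / n)
  out
}

#' Estimate the number of independent traits, block-wise
#'
#' For each measurement block (a complete donors x parameters matrix after
#' median imputation of residual missingness), counts the smallest number of
#' principal components of the standardized matrix whose cumulative explained
#' variance reaches `threshold`. The overall estimate aggregates blocks
#' conservatively by their maximum and is reported alongside the per-block
#' counts.
#'
#' @param blocks named list of numeric matrices (donors x parameters).
#' @param threshold cumulative variance threshold in `(0, 1]` (default 0.90).
#' @return list with `per_block` (named integer) and `overall`.
#' @export
estimate_independent_traits <- function(blocks, threshold = 0.90) {
  if (threshold <= 0 || threshold > 1) stop_config("threshold must be in (0,1]")
  if (is.null(names(blocks))) names(blocks) <- paste0("block", seq_along(blocks))
  per_block <- integer(0)
  for (bn in names(blocks)) {
    b <- as.matrix(blocks[[bn]])
    for (j in seq_len(ncol(b))) {
      nas <- is.na(b[, j])
      if (any(nas)) b[nas, j] <- stats::median(b[, j], na.rm = TRUE)
    }
    sds <- apply(b, 2L, stats::sd)
    b <- b[, is.finite(sds) & sds > 0, drop = FALSE]
    if (ncol(b) < 2L) {
      warning(sprintf("block '%s' has fewer than 2 informative parameters; skipped", bn))
      next
    }
    pc <- stats::prcomp(b, center = TRUE, scale. = TRUE)
    cumvar <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    per_block[bn] <- which(cumvar >= threshold - 1e-12)[1]
  }
  list(per_block = per_block,
       overall = if (length(per_block)) max(per_block) else NA_integer_)
}

#' Full phenotype QC pipeline
#'
#' Fixed order: per-column MAD cell filter, then per (channel, condition)
#' 2-D ICA sample filter, then per-column quantile transform.
#'
#' @param pheno donors x parameters matrix (dimnames required).
#' @param param_meta data.frame (parameter, channel, condition) mapping each
#'   column to its ICA block.
#' @param mad_k univariate MAD multiplier (default 4).
#' @param ica_k sample-level MAD multiplier (default 2.5).
#' @param seed seed for the ICA projections.
#' @return list: `matrix` (transformed, removed donors dropped), `cell_mask`
#'   (logical, TRUE = masked by the MAD filter), `removed_donors`
#'   (data.frame donor, reason), `report` (per-column removal counts).
#' @export
apply_phenotype_qc <- function(pheno, param_meta, mad_k = 4, ica_k = 2.5,
                               seed = 1) {
  stopifnot(!is.null(rownames(pheno)), !is.null(colnames(pheno)))
  mask <- matrix(FALSE, nrow(pheno), ncol(pheno), dimnames = dimnames(pheno))
  for (j in seq_len(ncol(pheno))) {
    if (all(is.na(pheno[, j]))) next
    mask[, j] <- mad_outlier_filter(pheno[, j], k = mad_k)
  }
  filtered <- pheno
  filtered[mask] <- NA_real_

  removed <- data.frame(donor = character(), reason = character(),
                        stringsAsFactors = FALSE)
  meta <- param_meta[match(colnames(pheno), param_meta$parameter), ]
  for (key in unique(paste(meta$channel, meta$condition, sep = "|"))) {
    cols <- which(paste(meta$channel, meta$condition, sep = "|") == key)
    if (length(cols) < 3L) next
    sub <- filtered[, cols, drop = FALSE]
    sub <- sub[, colSums(!is.na(sub)) > 0, drop = FALSE]
    if (ncol(sub) < 3L || nrow(sub) < 10L) next
    bad <- ica_sample_outlier_filter(sub, k = ica_k,
                                     seed = child_seed(seed, key))
    if (length(bad))
      removed <- rbind(removed, data.frame(
        donor = bad, reason = paste0("ica_outlier:", key),
        stringsAsFactors = FALSE))
  }
  keep <- !rownames(filtered) %in% removed$donor
  filtered <- filtered[keep, , drop = FALSE]

  transformed <- filtered
  for (j in seq_len(ncol(transformed))) {
    if (all(is.na(transformed[, j]))) next
    transformed[, j] <- suppressWarnings(quantile_transform(transformed[, j]))
  }
  report <- data.frame(parameter = colnames(pheno),
                       cells_masked = colSums(mask),
                       stringsAsFactors = FALSE)
  list(matrix = transformed, cell_mask = mask, removed_donors = removed,
       report = report)
}
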