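#' Covariate-adjusted linear association scan
#'
#' Per-variant ordinary least squares of a (quantile-transformed) trait on
#' allele dosage plus covariates. Covariates are variance-standardized;
#' collinear covariate columns are dropped with a warning. Variants without
#' missing dosages share one covariate projection (Frisch-Waugh-Lovell
#' residualization, numerically identical to the per-variant fit); variants
#' with missingness are fit by row omission. Two-sided p-values come from
#' the t distribution at the residual degrees of freedom and are floored at
#' 1e-320.
#'
#' @param trait numeric vector, one value per donor (NAs dropped).
#' @param geno a `genotype_matrix` (donors must align with `trait`).
#' @param covariates data.frame of covariates (factors allowed), or NULL.
#' @param trait_name label carried into the result.
#' @return data.frame: trait, variant, chrom, pos, beta, se, t, p, n.
#' @export
association_scan <- function(trait, geno, covariates = NULL,
                             trait_name = "trait") {
  g <- geno$dosage
  n_all <- nrow(g)
  stopifnot(length(trait) == n_all)

  x <- if (is.null(covariates) || !NCOL(covariates)) {
    matrix(1, n_all, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    mm <- stats::model.matrix(~ ., data = as.data.frame(covariates))
    sds <- apply(mm, 2L, stats::sd)
    scale_cols <- which(colnames(mm) != "(Intercept)" & sds > 0)
    mm[, scale_cols] <- scale(mm[, scale_cols, drop = FALSE])
    mm
  }
  rows_x <- stats::complete.cases(x) & !is.na(trait)
  y <- trait[rows_x]
  x <- x[rows_x, , drop = FALSE]
  gg <- g[rows_x, , drop = FALSE]

  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    drop_cols <- qx$pivot[(qx$rank + 1):ncol(x)]
    warning(sprintf("association_scan: dropping collinear covariate(s): %s",
                    paste(colnames(x)[drop_cols], collapse = ", ")))
    x <- x[, -drop_cols, drop = FALSE]
    qx <- qr(x)
  }
  p_cov <- ncol(x)
  n <- length(y)

  m <- ncol(gg)
  beta <- se <- tv <- pv <- rep(NA_real_, m)
  nv <- rep(NA_integer_, m)

  complete_v <- colSums(is.na(gg)) == 0L
  if (any(complete_v) && n >= p_cov + 2L) {
    ry <- qr.resid(qx, y)
    rg <- qr.resid(qx, gg[, complete_v, drop = FALSE])
    gty <- colSums(rg * ry)
    gtg <- colSums(rg^2)
    df <- n - p_cov - 1L
    b <- gty / gtg
    rss <- sum(ry^2) - b^2 * gtg
    s2 <- pmax(rss, 0) / df
    idx <- which(complete_v)
    beta[idx] <- b
    se[idx] <- sqrt(s2 / gtg)
    tv[idx] <- b / se[idx]
    pv[idx] <- p_from_t(tv[idx], df)
    nv[idx] <- n
  }
  for (j in which(!complete_v)) {
    ok <- !is.na(gg[, j])
    nj <- sum(ok)
    if (nj < p_cov + 2L) next
    xm <- cbind(x[ok, , drop = FALSE], dose = gg[ok, j])
    fit <- stats::lm.fit(xm, y[ok])
    if (fit$rank < ncol(xm)) next
    df <- nj - ncol(xm)
    s2 <- sum(fit$residuals^2) / df
    xtx_inv <- chol2inv(qr.R(fit$qr))
    beta[j] <- fit$coefficients["dose"]
    se[j] <- sqrt(s2 * xtx_inv[ncol(xm), ncol(xm)])
    tv[j] <- beta[j] / se[j]
    pv[j] <- p_from_t(tv[j], df)
    nv[j] <- nj
  }

  data.frame(trait = trait_name, variant = colnames(g),
             chrom = geno$variants$chrom, pos = geno$variants$pos,
             beta = beta, se = se, t = tv, p = pv, n = nv,
             stringsAsFactors = FALSE)
}

#' Scan many traits against one genotype panel
#'
#' @param traits donors x traits numeric matrix.
#' @param geno a `genotype_matrix`.
#' @param covariates as in [association_scan()].
#' @return rbind-ed scan results for all traits.
#' @export
association_scan_multi <- function(traits, geno, covariates = NULL) {
  res <- lapply(colnames(traits), function(tn) {
    association_scan(traits[, tn], geno, covariates, trait_name = tn)
  })
  if (!length(res))
    return(data.frame(trait = character(), variant = character(),
                      chrom = character(), pos = integer(), beta = numeric(),
                      se = numeric(), t = numeric(), p = numeric(),
                      n = integer(), stringsAsFactors = FALSE))
  do.call(rbind, res)
}
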