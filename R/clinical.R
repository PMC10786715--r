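#' Logistic association of a blood readout with a binary diagnosis
#'
#' `glm(outcome ~ readout + covariates, family = binomial)` on complete
#' cases; the readout coefficient is tested with a Wald z test. Cells with
#' fewer than 10 cases are skipped with a warning; separation or
#' non-convergence flags the cell and leaves the statistic missing.
#'
#' @param readout numeric vector (quantile-transformed upstream).
#' @param outcome 0/1 vector.
#' @param covariates data.frame (or NULL).
#' @return list: beta, z, p, n, cases, flag ("" when clean).
#' @export
fit_binary_assoc <- function(readout, outcome, covariates = NULL) {
  d <- data.frame(.y = outcome, .x = readout)
  if (!is.null(covariates)) d <- cbind(d, covariates)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  cases <- sum(d$.y == 1)
  empty <- list(beta = NA_real_, z = NA_real_, p = NA_real_, n = n,
                cases = cases, flag = "skipped")
  if (cases < 10L || n - cases < 1L) {
    warning(sprintf("fit_binary_assoc: %d cases < 10; skipped", cases))
    return(empty)
  }
  if (stats::sd(d$.x) == 0) {
    empty$flag <- "degenerate_readout"
    return(empty)
  }
  fit <- suppressWarnings(stats::glm(.y ~ ., data = d, family = stats::binomial()))
  co <- summary(fit)$coefficients
  if (!fit$converged || !".x" %in% rownames(co) || co[".x", "Std. Error"] > 100) {
    empty$flag <- "non_convergence_or_separation"
    return(empty)
  }
  z <- co[".x", "z value"]
  list(beta = co[".x", "Estimate"], z = z, p = p_from_z(z), n = n,
       cases = cases, flag = "")
}

#' Linear association of a blood readout with a continuous lab value
#'
#' Ordinary least squares with a t test on the readout coefficient.
#'
#' @inheritParams fit_binary_assoc
#' @param lab numeric outcome vector.
#' @return list: beta, t, p, n, flag.
#' @export
fit_continuous_assoc <- function(readout, lab, covariates = NULL) {
  d <- data.frame(.y = lab, .x = readout)
  if (!is.null(covariates)) d <- cbind(d, covariates)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  empty <- list(beta = NA_real_, t = NA_real_, p = NA_real_, n = n,
                flag = "degenerate")
  if (n < 3L || stats::sd(d$.x) == 0) return(empty)
  fit <- stats::lm(.y ~ ., data = d)
  co <- summary(fit)$coefficients
  if (!".x" %in% rownames(co)) return(empty)
  tval <- co[".x", "t value"]
  df <- fit$df.residual
  list(beta = co[".x", "Estimate"], t = tval,
       p = if (is.finite(tval)) p_from_t(tval, df) else P_FLOOR,
       n = n, flag = "")
}

#' Trait-by-endpoint association score matrix
#'
#' Fits every (blood trait, clinical endpoint) pair -- logistic models for
#' binary diagnoses (z statistics), linear models for continuous labs
#' (t statistics) -- with shared covariates, then controls FDR across all
#' cells with Storey q-values. The sign convention is positive statistic =
#' higher readout associated with higher outcome level.
#'
#' @param traits donors x traits matrix (quantile-transformed).
#' @param binary donors x diagnoses 0/1 matrix (may have 0 columns).
#' @param labs donors x labs numeric matrix (may have 0 columns).
#' @param covariates data.frame aligned with donors.
#' @return list of matrices `stat`, `p`, `q`, `n`, `cases` (traits x
#'   endpoints) plus `long` (one row per cell) and `pi0`.
#' @export
assoc_score_matrix <- function(traits, binary = NULL, labs = NULL,
                               covariates = NULL) {
  endpoints <- c(colnames(binary), colnames(labs))
  tn <- colnames(traits)
  shape <- list(tn, endpoints)
  stat <- p <- nmat <- cases <- matrix(NA_real_, length(tn), length(endpoints),
                                       dimnames = shape)
  rows <- list()
  for (ti in tn) {
    for (ei in endpoints) {
      if (!is.null(binary) && ei %in% colnames(binary)) {
        f <- suppressWarnings(fit_binary_assoc(traits[, ti], binary[, ei],
                                               covariates))
        stat[ti, ei] <- f$z
        cases[ti, ei] <- f$cases
        kind <- "binary"
      } else {
        f <- fit_continuous_assoc(traits[, ti], labs[, ei], covariates)
        stat[ti, ei] <- f$t
        kind <- "continuous"
      }
      p[ti, ei] <- f$p
      nmat[ti, ei] <- f$n
      rows[[length(rows) + 1L]] <- data.frame(
        trait = ti, endpoint = ei, kind = kind, beta = f$beta,
        stat = stat[ti, ei], p = f$p, n = f$n,
        cases = if (kind == "binary") f$cases else NA_real_,
        flag = f$flag, stringsAsFactors = FALSE)
    }
  }
  qv <- storey_qvalues(as.vector(p))
  q <- matrix(as.numeric(qv), nrow(p), ncol(p), dimnames = shape)
  long <- do.call(rbind, rows)
  long$q <- q[cbind(match(long$trait, tn), match(long$endpoint, endpoints))]
  list(stat = stat, p = p, q = q, n = nmat, cases = cases, long = long,
       pi0 = attr(qv, "pi0"))
}

#' ICA projection of the association score matrix
#'
#' Projects clinical endpoints into a 2-D independent-component space and
#' returns the mixing loadings of each blood trait; missing cells (skipped
#' models) are set to 0 with a mask recorded. Deterministic for a fixed
#' seed; components are ordered by descending mixing-variance and
#' sign-canonicalized.
#'
#' @param score traits x endpoints matrix of signed statistics.
#' @param n_comp components (default 2).
#' @param seed seed.
#' @return list: `coordinates` (endpoints x n_comp), `loadings` (traits x
#'   n_comp), `mask` (TRUE where a cell was missing), `ica` (full
#'   [fast_ica()] output).
#' @export
ica_project <- function(score, n_comp = 2, seed = 1) {
  score <- as.matrix(score)
  if (nrow(score) < 3L || ncol(score) < 3L)
    stop_config("ica_project: need >= 3 traits and >= 3 endpoints")
  mask <- is.na(score)
  score[mask] <- 0
  # rows = endpoints so the component scores are endpoint coordinates
  ic <- fast_ica(t(score), n_comp = n_comp, seed = seed)
  coords <- ic$s
  rownames(coords) <- colnames(score)
  colnames(coords) <- paste0("IC", seq_len(n_comp))
  loadings <- t(ic$a)
  rownames(loadings) <- rownames(score)
  colnames(loadings) <- paste0("IC", seq_len(n_comp))
  list(coordinates = coords, loadings = loadings, mask = mask, ica = ic)
}
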