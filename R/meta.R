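#' Random-effects meta-analysis of log hazard ratios
#'
#' Pools per-cohort estimates with a random-effects model; the
#' between-study variance tau-squared is estimated by restricted maximum
#' likelihood (via [metafor::rma()]), the pooled effect is the
#' inverse-variance weighted mean with weights `1 / (se^2 + tau2)`, and z
#' and two-sided p come from the normal approximation. A single study is
#' returned unchanged with tau2 = 0.
#'
#' @param estimates per-cohort log hazard ratios.
#' @param ses per-cohort standard errors (> 0).
#' @param labels optional cohort labels.
#' @return list: `pooled`, `pooled_se`, `tau2`, `z`, `p`, `per_study`
#'   (data.frame cohort, estimate, se).
#' @export
meta_random_effects <- function(estimates, ses, labels = NULL) {
  stopifnot(length(estimates) == length(ses), length(estimates) >= 1L,
            all(ses > 0))
  labels <- labels %||% paste0("cohort", seq_along(estimates))
  per_study <- data.frame(cohort = labels, estimate = estimates, se = ses,
                          stringsAsFactors = FALSE)
  if (length(estimates) == 1L) {
    z <- estimates / ses
    return(list(pooled = estimates, pooled_se = ses, tau2 = 0,
                z = z, p = p_from_z(z), per_study = per_study))
  }
  fit <- metafor::rma(yi = estimates, sei = ses, method = "REML")
  list(pooled = as.numeric(fit$beta), pooled_se = fit$se,
       tau2 = max(0, fit$tau2), z = as.numeric(fit$zval),
       p = max(as.numeric(fit$pval), P_FLOOR), per_study = per_study)
}

#' Meta-analyze a grid of score-endpoint models across cohorts
#'
#' @param grid data.frame with columns score, endpoint, cohort, loghr, se.
#' @return data.frame with one pooled row per (score, endpoint), including
#'   tau2, z, p and Storey q-values across the grid (Benjamini-Hochberg
#'   below 20 tests).
#' @export
meta_table <- function(grid) {
  stopifnot(all(c("score", "endpoint", "cohort", "loghr", "se") %in% names(grid)))
  keys <- unique(grid[, c("score", "endpoint")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    d <- grid[grid$score == keys$score[i] & grid$endpoint == keys$endpoint[i], ]
    m <- meta_random_effects(d$loghr, d$se, d$cohort)
    data.frame(score = keys$score[i], endpoint = keys$endpoint[i],
               k = nrow(d), pooled_loghr = m$pooled, pooled_se = m$pooled_se,
               tau2 = m$tau2, z = m$z, p = m$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- suppressWarnings(as.numeric(storey_qvalues(out$p)))
  out
}
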