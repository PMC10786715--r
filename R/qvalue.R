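#' Storey q-values
#'
#' Estimates the null proportion pi0 on the lambda grid 0.05..0.95 (step
#' 0.05) via `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))`, smooths the
#' profile with a cubic smoothing spline (df = 3) and extrapolates at the
#' largest lambda, clamping to (0, 1]. The q-value of each p is then
#' `min over p' >= p of pi0 * m * p' / rank(p')`, which is monotone
#' non-decreasing in p. With fewer than 20 p-values the pi0 estimate is
#' unstable and the function falls back to Benjamini-Hochberg (pi0 = 1) with
#' a warning; q-values with pi0 forced to 1 equal BH-adjusted p exactly.
#'
#' @param p vector of p-values in (0, 1].
#' @param lambda grid for the pi0 profile.
#' @param pi0 optionally force pi0 (e.g. 1 for BH).
#' @return q-values (same order as `p`), with `pi0` attached as an attribute.
#' @export
storey_qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05), pi0 = NULL) {
  ok <- !is.na(p)
  pv <- p[ok]
  if (any(pv <= 0 | pv > 1)) stop_config("p-values must lie in (0, 1]")
  m <- length(pv)
  if (is.null(pi0)) {
    if (m < 20L) {
      warning("storey_qvalues: fewer than 20 p-values; falling back to BH (pi0 = 1)")
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda, function(l) sum(pv > l) / (m * (1 - l)), numeric(1))
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(fit, x = max(lambda))$y
      pi0 <- min(max(pi0, 1e-8), 1)
    }
  }
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pi0 * m * pv[o] / rank(pv, ties.method = "max")[o]))[ro]
  out <- rep(NA_real_, length(p))
  out[ok] <- q
  attr(out, "pi0") <- pi0
  out
}
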