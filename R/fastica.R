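#' Fixed-point independent component analysis
#'
#' Symmetric (parallel) fixed-point ICA with the logcosh contrast, used both
#' for the sample-level phenotype outlier projection and for the projection of
#' the trait-by-endpoint association score matrix. The input is centred and
#' whitened by SVD; unmixing vectors are updated jointly and re-orthogonalised
#' by symmetric decorrelation until the update angle falls below `tol`.
#'
#' Estimation is deterministic for a fixed `seed` (the seed only sets the
#' random orthogonal initialisation). If the fixed-point iteration fails to
#' converge, up to `restarts` fresh initialisations are attempted before
#' erroring. Near-Gaussian inputs are weakly identifiable for ICA; when every
#' whitened column has excess kurtosis below 0.1 in magnitude a message is
#' emitted but estimation proceeds.
#'
#' @param x numeric matrix (observations in rows), at least `n_comp` columns.
#' @param n_comp number of components to extract (default 2).
#' @param alpha logcosh slope in `[1, 2]`.
#' @param max_iter,tol fixed-point iteration controls.
#' @param seed integer seed for the random initial unmixing matrix.
#' @param restarts maximum number of re-initialisations on non-convergence.
#' @return list with `s` (n x n_comp estimated sources, unit variance),
#'   `a` (n_comp x p mixing matrix, so `s %*% a` approximates the centred
#'   input), `w` (unmixing applied to whitened data), `k` (whitening matrix),
#'   `center`, `converged`, `iterations`, `weakly_identifiable`.
#' @export
fast_ica <- function(x, n_comp = 2, alpha = 1, max_iter = 200, tol = 1e-8,
                     seed = 1, restarts = 5) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  p <- ncol(x)
  if (n < 2L || p < n_comp)
    stop_config("fast_ica: need >= 2 rows and >= %d columns", n_comp)
  center <- colMeans(x)
  xc <- sweep(x, 2L, center)

  sv <- svd(xc, nu = n_comp, nv = n_comp)
  pos <- sv$d > max(sv$d[1], 1) * 1e-10
  if (sum(pos) < n_comp)
    stop_config("fast_ica: input rank %d below requested %d components",
                sum(pos), n_comp)
  # whitening: z has identity sample covariance
  k <- sv$v[, seq_len(n_comp), drop = FALSE] %*%
    diag(sqrt(n - 1) / sv$d[seq_len(n_comp)], n_comp)
  z <- xc %*% k

  kurt <- apply(z, 2L, function(v) mean(v^4) / mean(v^2)^2 - 3)
  weak <- all(abs(kurt) < 0.1)
  if (weak)
    message("fast_ica: whitened input is near-Gaussian; components are weakly identifiable")

  sym_decorrelate <- function(w) {
    e <- eigen(w %*% t(w), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)), n_comp) %*%
      t(e$vectors) %*% w
  }

  converged <- FALSE
  iterations <- 0L
  w <- NULL
  for (r in seq_len(restarts)) {
    set.seed(child_seed(seed, paste0("fast_ica_restart_", r)))
    w0 <- sym_decorrelate(matrix(stats::rnorm(n_comp * n_comp), n_comp))
    for (it in seq_len(max_iter)) {
      y <- z %*% t(w0)                        # n x c
      gy <- tanh(alpha * y)
      w1 <- crossprod(gy, z) / n - diag(colMeans(alpha * (1 - gy^2)), n_comp) %*% w0
      w1 <- sym_decorrelate(w1)
      delta <- max(abs(1 - abs(rowSums(w1 * w0))))
      w0 <- w1
      if (delta < tol) { converged <- TRUE; iterations <- it; break }
    }
    if (converged) { w <- w0; break }
  }
  if (!converged)
    stop_config("fast_ica: no convergence after %d restarts of %d iterations",
                restarts, max_iter)

  s <- z %*% t(w)
  a <- solve(crossprod(s), crossprod(s, xc))   # least-squares mixing matrix

  # canonical order: descending variance of the mixing-matrix rows;
  # canonical sign: the largest-magnitude loading of each component positive
  ord <- order(apply(a, 1L, stats::var), decreasing = TRUE)
  s <- s[, ord, drop = FALSE]
  a <- a[ord, , drop = FALSE]
  w <- w[ord, , drop = FALSE]
  for (j in seq_len(n_comp)) {
    flip <- sign(a[j, which.max(abs(a[j, ]))])
    if (flip < 0) { s[, j] <- -s[, j]; a[j, ] <- -a[j, ]; w[j, ] <- -w[j, ] }
  }

  list(s = s, a = a, w = w, k = k, center = center, converged = converged,
       iterations = iterations, weakly_identifiable = weak)
}
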