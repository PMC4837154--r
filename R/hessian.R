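## Central finite-difference Hessian with per-coordinate steps, and the
## positive-definite repair used before inverting curvature matrices.

#' Finite-difference Hessian
#'
#' Central second differences with per-coordinate adaptive steps
#' (`h_i = step_frac * (1 + |x_i|)`); the result is symmetrised.
#'
#' @param fn Scalar function.
#' @param x Point of evaluation.
#' @param step_frac Relative step size (default `6e-5 ~ eps^(1/3) / 10`... a
#'   compromise between truncation and cancellation error for log-likelihood
#'   scale functions).
#' @return A symmetric numeric matrix.
#' @export
fd_hessian <- function(fn, x, step_frac = 1e-4) {
  n <- length(x)
  h <- step_frac * (1 + abs(x))
  H <- matrix(NA_real_, n, n)
  f0 <- fn(x)
  for (i in seq_len(n)) {
    ei <- numeric(n); ei[i] <- h[i]
    fpp <- fn(x + ei); fmm <- fn(x - ei)
    H[i, i] <- (fpp - 2 * f0 + fmm) / h[i]^2
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        ej <- numeric(n); ej[j] <- h[j]
        fpq <- fn(x + ei + ej); fpm <- fn(x + ei - ej)
        fmp <- fn(x - ei + ej); fmq <- fn(x - ei - ej)
        H[i, j] <- H[j, i] <- (fpq - fpm - fmp + fmq) / (4 * h[i] * h[j])
      }
    }
  }
  (H + t(H)) / 2
}

#' Repair a covariance/precision matrix to positive definiteness
#'
#' Adds the smallest ridge `delta * I` that lifts the minimum eigenvalue to
#' `min_eig`, flagging whether a repair was needed.
#'
#' @param M Symmetric matrix.
#' @param min_eig Target minimum eigenvalue.
#' @return A list: `M` (repaired matrix), `repaired` (logical),
#'   `ridge` (the delta added).
#' @export
pd_repair <- function(M, min_eig = 1e-8) {
  M <- (M + t(M)) / 2
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  lam_min <- min(ev)
  if (is.finite(lam_min) && lam_min >= min_eig)
    return(list(M = M, repaired = FALSE, ridge = 0))
  ridge <- min_eig - lam_min
  if (!is.finite(ridge)) stop_param("curvature matrix has non-finite entries")
  list(M = M + diag(ridge, nrow(M)), repaired = TRUE, ridge = ridge)
}
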