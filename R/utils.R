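`%||%` <- function(a, b) if (is.null(a)) b else a

#' Symmetric matrix square root
#'
#' Eigen-based square root of a symmetric positive semi-definite matrix.
#' Small negative eigenvalues (numerical noise) are truncated at zero.
#'
#' @param S symmetric PSD matrix.
#' @return A symmetric matrix `M` with `M %*% M = S`.
#' @keywords internal
mat_sqrt <- function(S) {
  S <- as.matrix(S)
  if (nrow(S) == 1L) return(matrix(sqrt(max(S[1L, 1L], 0)), 1L, 1L))
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

# Linear transform of the columns of X so the empirical covariance of the
# result equals `target` exactly. Used to give simulated breeding values a
# realized genomic (co)variance identical to the configured one.
exact_cov_transform <- function(X, target) {
  X <- as.matrix(X)
  Xc <- sweep(X, 2L, colMeans(X))
  S <- stats::cov(Xc)
  es <- eigen(S, symmetric = TRUE)
  keep <- es$values > max(es$values, 0) * 1e-10
  if (!any(keep)) stop("raw scores are numerically constant; cannot rescale")
  isqrt <- es$vectors[, keep, drop = FALSE] %*%
    (t(es$vectors[, keep, drop = FALSE]) / sqrt(es$values[keep]))
  (Xc %*% isqrt) %*% mat_sqrt(target)
}

is_symmetric_psd <- function(S, tol = 1e-8) {
  S <- as.matrix(S)
  if (!isSymmetric(S, tol = 1e-8)) return(FALSE)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= -tol * max(abs(ev), 1)
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  invisible(x)
}
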