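# internal numerical helpers

# Moore-Penrose pseudoinverse via SVD with relative tolerance
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

mat_rank <- function(A, tol = 1e-10) {
  d <- svd(A, nu = 0, nv = 0)$d
  sum(d > tol * max(d, 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
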