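#' Between-subjects design specification
#'
#' Pairs a subjects-by-predictors design matrix `G` with a
#' contrasts-by-predictors contrast matrix `C` defining the null hypothesis
#' `C B = 0` on the regression coefficients.
#'
#' @param G numeric subjects x predictors matrix.
#' @param C numeric contrasts x predictors matrix (>= 1 row).
#' @param labels optional predictor labels.
#' @return object of class `fcmvpa_design`.
#' @export
design_spec <- function(G, C, labels = colnames(G)) {
  G <- as.matrix(G); C <- matrix(C, ncol = ncol(G))
  stopifnot(nrow(C) >= 1, ncol(C) == ncol(G), mat_rank(C) >= 1)
  structure(list(G = G, C = C, labels = labels), class = "fcmvpa_design")
}

#' Ordinary least squares fit of a multivariate GLM
#'
#' Fits `Y = G B + E` by OLS (pseudoinverse, so rank-deficient designs are
#' handled) and accumulates the residual sum-of-squares-and-products matrix
#' `W = (Y - G B)'(Y - G B)`. The error degrees of freedom are
#' `b = N - rank(G)`.
#'
#' @param G subjects x predictors design matrix.
#' @param Y subjects x dims response matrix (eigenpattern scores, or raw
#'   connectivity rows).
#' @return object of class `fcmvpa_fit`: `B` (predictors x dims), `W`,
#'   `residuals`, `b`, `rank_G`, `G`, `sigma` (`W / b`).
#' @export
fit_ols <- function(G, Y) {
  G <- as.matrix(G); Y <- as.matrix(Y)
  stopifnot(nrow(G) == nrow(Y))
  rG <- mat_rank(G)
  b <- nrow(G) - rG
  if (b < 1) stop("no residual degrees of freedom: N <= rank(G)")
  B <- pinv(G) %*% Y
  E <- Y - G %*% B
  W <- crossprod(E)
  structure(list(B = B, W = W, residuals = E, b = b, rank_G = rG, G = G,
                 sigma = W / b),
            class = "fcmvpa_fit")
}

#' Hypothesis sum-of-squares-and-products matrix
#'
#' `H = (C B)' (C (G'G)^- C')^{-1} (C B)` on the response subspace of the
#' fit: the between-hypothesis counterpart of the residual SSCP `W`.
#'
#' @param fit an `fcmvpa_fit` from [fit_ols()].
#' @param C contrasts x predictors matrix.
#' @return symmetric positive semidefinite dims x dims matrix.
#' @export
hypothesis_sscp <- function(fit, C) {
  C <- matrix(C, ncol = nrow(fit$B))
  if (all(C == 0)) return(matrix(0, ncol(fit$B), ncol(fit$B)))
  M <- C %*% pinv(crossprod(fit$G)) %*% t(C)
  if (rcond(M) < 1e-12)
    stop("contrast is not estimable under this design (singular C (G'G)^- C')")
  CB <- C %*% fit$B
  t(CB) %*% solve(M, CB)
}

# shared Rao coefficients for the Wilks-Lambda F approximation
.rao_coef <- function(a, b, c) {
  num <- a^2 * c^2 - 4
  den <- a^2 + c^2 - 5
  e <- if (num > 0 && den > 0) sqrt(num / den) else 1
  list(e = e, df1 = a * c, df2 = (b - (a - c + 1) / 2) * e - a * c / 2 + 1)
}

#' Wilks' Lambda likelihood-ratio F test
#'
#' Computes `lambda = det(W) / det(W + H)` and Rao's F approximation:
#' `F = (df2 / df1) (1 - lambda^(1/e)) / lambda^(1/e)` with `df1 = a c`,
#' `df2 = (b - (a - c + 1)/2) e - a c / 2 + 1` and
#' `e = sqrt((a^2 c^2 - 4) / (a^2 + c^2 - 5))` (set to 1 when either term is
#' nonpositive -- the convention under which the small-dimension cases are
#' exactly F-distributed; at `a = c = 1` the statistic reduces exactly to the
#' ordinary univariate F). Under the null, `F ~ F(df1, df2)`.
#'
#' Determinants are evaluated through Cholesky log-determinants for
#' stability. Requires `a < b`: once the number of response dimensions
#' reaches the error degrees of freedom, `W` is rank deficient and the
#' likelihood ratio test assumptions no longer hold.
#'
#' @param W residual SSCP (a x a).
#' @param H hypothesis SSCP (a x a).
#' @param a number of response dimensions (rank of the response subspace).
#' @param b error degrees of freedom, `N - rank(G)`.
#' @param c hypothesis degrees of freedom, `rank(C)`.
#' @return list with `F`, `df1`, `df2`, `lambda`, `e`, `p` (upper tail).
#' @export
wilks_lrt_f <- function(W, H, a, b, c) {
  stopifnot(a >= 1, c >= 1)
  if (a >= b)
    stop("a >= b: response dimensionality reaches the error degrees of ",
         "freedom; likelihood ratio test assumptions no longer hold")
  cw <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(cw)) stop("W is numerically singular; lambda is degenerate")
  cwh <- tryCatch(chol(W + H), error = function(e) NULL)
  if (is.null(cwh)) stop("W + H is numerically singular")
  loglam <- 2 * (sum(log(diag(cw))) - sum(log(diag(cwh))))
  loglam <- min(loglam, 0)
  lambda <- exp(loglam)
  if (!is.finite(lambda) || lambda <= 0)
    stop("degenerate Wilks lambda (<= 0)")
  rc <- .rao_coef(a, b, c)
  le <- exp(loglam / rc$e)
  Fv <- max(0, rc$df2 / rc$df1 * (1 - le) / le)
  list(F = Fv, df1 = rc$df1, df2 = rc$df2, lambda = lambda, e = rc$e,
       p = pf(Fv, rc$df1, rc$df2, lower.tail = FALSE))
}

#' Satterthwaite-approximated trace F test
#'
#' The high-dimensional omnibus test `F = (b / c) tr(H) / tr(W)`, referred to
#' an F distribution with `k c` and `k b` degrees of freedom where
#' `k = tr(W)^2 / tr(W^2)` is the Satterthwaite effective dimensionality
#' (1 for a one-dimensional response, `v` for `W` proportional to a v-dim
#' identity). Used when the response dimensionality exceeds what the Wilks
#' statistic can support (e.g. full connectivity rows).
#'
#' @param W residual SSCP.
#' @param H hypothesis SSCP.
#' @param b error degrees of freedom.
#' @param c hypothesis degrees of freedom.
#' @return list with `F`, `df1`, `df2`, `k_eff`, `p`.
#' @export
satterthwaite_f <- function(W, H, b, c) {
  trW <- sum(diag(as.matrix(W)))
  if (trW <= 0) stop("tr(W) <= 0: residual covariance is degenerate")
  trW2 <- sum(as.matrix(W)^2)
  k_eff <- trW^2 / trW2
  Fv <- (b / c) * sum(diag(as.matrix(H))) / trW
  list(F = Fv, df1 = k_eff * c, df2 = k_eff * b, k_eff = k_eff,
       p = pf(Fv, k_eff * c, k_eff * b, lower.tail = FALSE))
}

#' Univariate GLM test for one connection
#'
#' Ordinary GLM t/F test of a single connectivity value across subjects:
#' the mass-univariate building block, one test per (seed, target) pair.
#' Equals the Wilks likelihood-ratio F with a one-dimensional response.
#'
#' @param r numeric vector of per-subject connectivity values.
#' @param design an `fcmvpa_design`.
#' @return list with `F`, `t` (when the contrast has one row), `df1`, `df2`,
#'   `p`.
#' @export
mua_stat <- function(r, design) {
  fit <- fit_ols(design$G, matrix(r, ncol = 1))
  H <- hypothesis_sscp(fit, design$C)
  c_df <- mat_rank(design$C)
  if (drop(fit$W) == 0 && drop(H) == 0)
    return(list(F = 0, t = 0, df1 = c_df, df2 = fit$b, p = 1))
  Fv <- drop(H) / c_df / (drop(fit$W) / fit$b)
  tv <- if (nrow(design$C) == 1) {
    se <- sqrt(drop(design$C %*% pinv(crossprod(fit$G)) %*% t(design$C)) *
                 drop(fit$W) / fit$b)
    drop(design$C %*% fit$B) / se
  } else NA_real_
  list(F = Fv, t = tv, df1 = c_df, df2 = fit$b,
       p = pf(Fv, c_df, fit$b, lower.tail = FALSE))
}

#' Voxelwise multivariate-pattern statistic map
#'
#' The whole-brain inference step: at every seed voxel, the subjects x k
#' eigenpattern scores are entered as responses of the multivariate GLM
#' `s_n = g_n B + e_n`, and the contrast `C B = 0` is tested with the Wilks
#' likelihood-ratio F ([wilks_lrt_f()]) with `a = k`. Requires
#' `k < N - rank(G)`.
#'
#' @param scores `fcmvpa_scores` from [efficient_scores()].
#' @param design an `fcmvpa_design`.
#' @return object of class `fcmvpa_statmap`: vectors `F`, `p`, `lambda` over
#'   voxels plus `df1`, `df2`, `k`, `stat = "wilks"`.
#' @export
mvpa_statmap <- function(scores, design) {
  stopifnot(inherits(scores, "fcmvpa_scores"), inherits(design, "fcmvpa_design"))
  V <- scores$n_voxels
  k <- scores$k
  b <- nrow(design$G) - mat_rank(design$G)
  if (k >= b)
    stop(sprintf("k = %d >= error dof b = %d: choose fewer eigenpatterns", k, b))
  c_df <- mat_rank(design$C)
  Fv <- pv <- lam <- rep(NA_real_, V)
  df1 <- df2 <- NA_real_
  for (x in seq_len(V)) {
    fit <- fit_ols(design$G, scores$scores[, , x])
    H <- hypothesis_sscp(fit, design$C)
    w <- wilks_lrt_f(fit$W, H, a = k, b = fit$b, c = c_df)
    Fv[x] <- w$F; pv[x] <- w$p; lam[x] <- w$lambda
    df1 <- w$df1; df2 <- w$df2
  }
  structure(list(F = Fv, p = pv, lambda = lam, df1 = df1, df2 = df2,
                 k = k, stat = "wilks"),
            class = "fcmvpa_statmap")
}

#' @export
print.fcmvpa_statmap <- function(x, ...) {
  cat(sprintf("fcmvpa statistic map (%s): %d voxels, F(%g, %g), max F = %.2f, min p = %.2e\n",
              x$stat, length(x$F), x$df1, x$df2, max(x$F, na.rm = TRUE),
              min(x$p, na.rm = TRUE)))
  invisible(x)
}

#' Voxelwise multivariate statistic map with an explicit spatial contrast
#'
#' The general multivariate analysis: at every seed voxel the full
#' connectivity rows `R(x)` are projected through a between-voxels contrast
#' `P` and the contrast `C B P = 0` is tested. `P = "identity"` keeps all
#' target voxels and uses the Satterthwaite trace F ([satterthwaite_f()]);
#' a single-column `P` concentrated on one target voxel reduces exactly to a
#' seed-based connectivity (univariate) analysis; a low-dimensional `P`
#' (columns < error dof) uses the Wilks likelihood-ratio F, so choosing the
#' eigenpatterns scaled by their inverse singular values reproduces
#' [mvpa_statmap()] exactly.
#'
#' @param sessions list of [bold_session()].
#' @param design an `fcmvpa_design`.
#' @param P `"identity"`, a voxels x q matrix, or a `function(x)` returning
#'   one (possibly different per seed voxel).
#' @param voxels seed voxels to evaluate (default all).
#' @return `fcmvpa_statmap` with `stat` `"satterthwaite"` or `"wilks"`.
#' @export
mva_statmap <- function(sessions, design, P = "identity",
                        voxels = NULL) {
  V <- ncol(normalize_timeseries(sessions[[1]]))
  voxels <- voxels %||% seq_len(V)
  b <- nrow(design$G) - mat_rank(design$G)
  c_df <- mat_rank(design$C)
  getP <- if (is.function(P)) P else function(x) P
  Fv <- pv <- lam <- rep(NA_real_, length(voxels))
  df1 <- df2 <- NA_real_; stat <- NULL
  for (i in seq_along(voxels)) {
    x <- voxels[i]
    R <- stack_rows(sessions, x)
    Px <- getP(x)
    if (identical(Px, "identity")) {
      fit <- fit_ols(design$G, R)
      H <- hypothesis_sscp(fit, design$C)
      s <- satterthwaite_f(fit$W, H, b = fit$b, c = c_df)
      stat <- "satterthwaite"
    } else {
      Px <- as.matrix(Px)
      if (ncol(Px) < 1) stop("between-voxels contrast P has zero columns")
      Y <- R %*% Px
      fit <- fit_ols(design$G, Y)
      H <- hypothesis_sscp(fit, design$C)
      a <- mat_rank(Px)
      s <- wilks_lrt_f(fit$W, H, a = a, b = fit$b, c = c_df)
      lam[i] <- s$lambda
      stat <- "wilks"
    }
    Fv[i] <- s$F; pv[i] <- s$p; df1 <- s$df1; df2 <- s$df2
  }
  structure(list(F = Fv, p = pv, lambda = lam, df1 = df1, df2 = df2,
                 k = NA_integer_, stat = stat, voxels = voxels),
            class = "fcmvpa_statmap")
}
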