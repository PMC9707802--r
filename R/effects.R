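#' Post-hoc effect sizes for a cluster
#'
#' Characterises, for a significant region `omega` and a single contrast row
#' `c_j`, the departures from the null hypothesis on three scales:
#' `h_eig`, the per-eigenpattern contrast effects accumulated over the
#' region's voxels; `h_scores`, the per-subject weighting vector obtained by
#' mapping each voxel's effect back through its score matrix; and `h_map`,
#' the per-target-voxel effect map obtained by further mapping through the
#' connectivity rows. In the full-rank limit `k = N`, `h_scores` collapses
#' to the constant vector `c_j (G'G)^{-1} G'` and `h_map` equals the
#' post-hoc seed-based-connectivity effect map exactly.
#'
#' These are post-hoc estimates computed on the same data that selected the
#' region, and therefore biased; they are intended for interpretation and
#' hypothesis building, not secondary inference. For unbiased estimates use
#' `split_sessions` to supply an independent subject set from which the
#' effects (but not the region) are computed.
#'
#' @param sessions list of [bold_session()].
#' @param design an `fcmvpa_design`.
#' @param contrast single contrast row over predictors (defaults to the
#'   first row of `design$C`).
#' @param omega integer vector of region voxel indices (nonempty).
#' @param k number of eigenpatterns used per voxel.
#' @param normalize `"sum"` (plain accumulation over voxels) or `"mean"`
#'   (divide by the region size, for cross-cluster comparability).
#' @param split_sessions optional independent sessions from which effects
#'   are estimated (cross-validated variant); the region is taken as given.
#' @return object of class `fcmvpa_effects`: `h_eig` (length k),
#'   `h_scores` (length N), `h_map` (length n_voxels), `omega`, `k`,
#'   `posthoc = is.null(split_sessions)`.
#' @export
effect_sizes <- function(sessions, design, contrast = design$C[1, ],
                         omega, k, normalize = c("sum", "mean"),
                         split_sessions = NULL) {
  normalize <- match.arg(normalize)
  stopifnot(length(omega) >= 1)
  use <- split_sessions %||% sessions
  cj <- matrix(contrast, nrow = 1)
  N <- length(use)
  if (nrow(design$G) != N)
    stop("design has ", nrow(design$G), " rows but ", N,
         " sessions are used; supply a design matching the estimation set")
  V <- ncol(normalize_timeseries(use[[1]]))
  if (any(omega < 1 | omega > V)) stop("region omega lies outside the mask")
  pG <- pinv(design$G)
  h_eig <- numeric(k); h_scores <- numeric(N); h_map <- numeric(V)
  for (x in omega) {
    R <- stack_rows(use, x)
    basis <- voxel_svd(R, k = k)
    if (basis$k < k) stop("mismatched k between fit and basis")
    Btil <- pG %*% basis$scores                      # predictors x k
    he_x <- drop(cj %*% Btil)                        # k
    hs_x <- drop(he_x %*% t(basis$scores))           # N
    h_eig <- h_eig + he_x
    h_scores <- h_scores + hs_x
    h_map <- h_map + drop(hs_x %*% R)                # V
  }
  if (normalize == "mean") {
    h_eig <- h_eig / length(omega)
    h_scores <- h_scores / length(omega)
    h_map <- h_map / length(omega)
  }
  structure(list(h_eig = h_eig, h_scores = h_scores, h_map = h_map,
                 omega = omega, k = as.integer(k),
                 posthoc = is.null(split_sessions)),
            class = "fcmvpa_effects")
}

#' @export
print.fcmvpa_effects <- function(x, ...) {
  cat(sprintf("fcmvpa %s effect sizes: region of %d voxels, k = %d\n",
              if (x$posthoc) "post-hoc (biased)" else "cross-validated",
              length(x$omega), x$k))
  cat("  h_eig:", signif(x$h_eig, 3), "\n")
  invisible(x)
}

#' Post-hoc seed-based-connectivity effect map
#'
#' The simple alternative effect-size report: the ordinary univariate GLM
#' contrast effect `c_j (G'G)^- G' rbar` fitted to the mean-over-region seed
#' connectivity rows, one value per target voxel. Agrees with the
#' [effect_sizes()] `h_map` in the full-rank (`k = N`) limit for singleton
#' regions, and is proportional to it for larger regions.
#'
#' @inheritParams effect_sizes
#' @return numeric effect vector over target voxels.
#' @export
sbc_posthoc_map <- function(sessions, design, contrast = design$C[1, ],
                            omega) {
  stopifnot(length(omega) >= 1)
  cj <- matrix(contrast, nrow = 1)
  Rbar <- NULL
  for (x in omega) {
    R <- stack_rows(sessions, x)
    Rbar <- if (is.null(Rbar)) R else Rbar + R
  }
  Rbar <- Rbar / length(omega)
  drop(cj %*% pinv(design$G) %*% Rbar)
}
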