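#' Per-voxel SVD eigenpattern basis
#'
#' Factorises the uncentred stacked connectivity matrix `R = S D P'` for one
#' seed voxel. The columns of `P` (returned as rows of `patterns`) are the
#' seed's *eigenpatterns*: mutually orthonormal spatial modes of intersubject
#' variability in connectivity with that seed. The rows of `S` are the
#' per-subject *eigenpattern scores*, the low-dimensional representation that
#' enters the group-level model. `xi` gives the explained-covariance
#' fractions: squared singular values divided by `trace(R R')`, so they sum
#' to one over all components.
#'
#' `R` is deliberately not mean-centred before the decomposition (a pure SVD
#' rather than a PCA of centred data), so the first eigenpattern typically
#' tracks the average connectivity map; `center = TRUE` is available for
#' exploration. Component signs are fixed deterministically: each score
#' column is flipped so its sum is nonnegative (equivalently, so the
#' eigenpattern correlates nonnegatively with the subject-mean connectivity
#' row); exact ties fall back to making the first nonzero pattern element
#' positive.
#'
#' @param R subjects x voxels matrix from [stack_rows()].
#' @param k number of components to retain; default all (up to rank).
#' @param center centre columns of `R` before decomposing (default `FALSE`).
#' @return object of class `fcmvpa_eigenbasis`: `scores` (subjects x k,
#'   orthonormal columns), `singular_values` (length k, decreasing),
#'   `patterns` (k x voxels, orthonormal rows), `xi` (length k),
#'   `xi_full` (all components), `k`, `seed_index`.
#' @export
voxel_svd <- function(R, k = NULL, center = FALSE) {
  R <- as.matrix(R)
  if (center) R <- sweep(R, 2L, colMeans(R), "-")
  sv <- svd(R)
  tol <- max(dim(R)) * .Machine$double.eps * max(sv$d)
  rnk <- sum(sv$d > tol)
  if (is.null(k)) k <- rnk
  if (k > rnk)
    stop(sprintf("k = %d exceeds the achievable rank %d of R", k, rnk))
  d2 <- sv$d^2
  xi_full <- d2 / sum(d2)
  S <- sv$u[, seq_len(k), drop = FALSE]
  P <- sv$v[, seq_len(k), drop = FALSE]
  # deterministic sign convention
  for (j in seq_len(k)) {
    cs <- sum(S[, j])
    flip <- if (abs(cs) > 1e-12) cs < 0 else {
      nz <- which(abs(P[, j]) > 1e-12)[1]
      !is.na(nz) && P[nz, j] < 0
    }
    if (isTRUE(flip)) { S[, j] <- -S[, j]; P[, j] <- -P[, j] }
  }
  structure(list(scores = S, singular_values = sv$d[seq_len(k)],
                 patterns = t(P), xi = xi_full[seq_len(k)],
                 xi_full = xi_full, k = as.integer(k),
                 seed_index = attr(R, "seed_index") %||% NA_integer_),
            class = "fcmvpa_eigenbasis")
}

#' Eigenpattern scores for every seed voxel via the timeseries path
#'
#' Computes, for every seed voxel simultaneously, the same eigenpattern
#' scores, singular values and explained-covariance fractions as running
#' [voxel_svd()] on [stack_rows()] seed by seed -- but through temporal
#' cross-products, so that no voxels-by-voxels matrix is ever materialised
#' and the cost grows linearly (not quadratically) in the number of voxels.
#'
#' With unit-normalised series `Z_n` (time x voxel), the `(n, m)` entry of
#' the seed-voxel Gram matrix `R(x) R'(x)` equals
#' `z_n(x)' (Z_n Z_m') z_m(x)`. The time-by-time blocks `Z_n Z_m'` are formed
#' once for all subject pairs and contracted against the seed columns for a
#' block of seed voxels at a time (`block_size` controls peak memory); the
#' scores at each seed are then the leading eigenvectors of its Gram matrix.
#'
#' @param sessions list of [bold_session()] sharing a mask.
#' @param k number of components to retain per voxel.
#' @param block_size number of seed voxels processed per block.
#' @param center centre `R(x)` columns first (must match [voxel_svd()] use).
#' @return object of class `fcmvpa_scores`: `scores` (subjects x k x voxels
#'   array), `singular_values` (k x voxels), `xi` (k x voxels), `k`,
#'   `subject_ids`, `n_voxels`.
#' @export
efficient_scores <- function(sessions, k, block_size = 512L, center = FALSE) {
  N <- length(sessions)
  stopifnot(N >= 2, k >= 1, k <= N)
  Z <- lapply(sessions, normalize_timeseries)
  Tt <- nrow(Z[[1]]); V <- ncol(Z[[1]])
  stopifnot(all(vapply(Z, ncol, 0L) == V))
  if (center)
    return(.efficient_scores_centered(sessions, Z, k, block_size))
  Zbig <- do.call(rbind, Z)                      # (N*T) x V
  Q <- tcrossprod(Zbig)                          # (N*T) x (N*T), blocks Z_n Z_m'
  subj <- rep(seq_len(N), each = Tt)
  scores <- array(NA_real_, c(N, k, V))
  dvals <- matrix(NA_real_, k, V)
  xi <- matrix(NA_real_, k, V)
  blocks <- split(seq_len(V), ceiling(seq_len(V) / block_size))
  for (bl in blocks) {
    Gb <- array(0, c(N, N, length(bl)))
    for (m in seq_len(N)) {
      cols <- ((m - 1) * Tt + 1):(m * Tt)
      Am <- Q[, cols, drop = FALSE] %*% Z[[m]][, bl, drop = FALSE]  # NT x |bl|
      Gb[, m, ] <- rowsum(Am * Zbig[, bl, drop = FALSE], subj)
    }
    for (i in seq_along(bl)) {
      eg <- eigen(Gb[, , i], symmetric = TRUE)
      ev <- pmax(eg$values, 0)
      S <- eg$vectors[, seq_len(k), drop = FALSE]
      for (j in seq_len(k)) if (sum(S[, j]) < 0) S[, j] <- -S[, j]
      scores[, , bl[i]] <- S
      dvals[, bl[i]] <- sqrt(ev[seq_len(k)])
      xi[, bl[i]] <- ev[seq_len(k)] / sum(ev)
    }
  }
  structure(list(scores = scores, singular_values = dvals, xi = xi,
                 k = as.integer(k),
                 subject_ids = vapply(sessions, function(s)
                   if (inherits(s, "fcmvpa_session")) s$subject_id else "subj",
                   character(1)),
                 n_voxels = V),
            class = "fcmvpa_scores")
}

# centred variant: falls back to the direct per-voxel path (centring breaks
# the pure cross-product contraction; used for exploration only)
.efficient_scores_centered <- function(sessions, Z, k, block_size) {
  N <- length(Z); V <- ncol(Z[[1]])
  scores <- array(NA_real_, c(N, k, V))
  dvals <- matrix(NA_real_, k, V); xi <- matrix(NA_real_, k, V)
  for (x in seq_len(V)) {
    b <- voxel_svd(stack_rows(sessions, x), k = k, center = TRUE)
    scores[, , x] <- b$scores
    dvals[, x] <- b$singular_values
    xi[, x] <- b$xi
  }
  structure(list(scores = scores, singular_values = dvals, xi = xi,
                 k = as.integer(k),
                 subject_ids = vapply(sessions, function(s)
                   if (inherits(s, "fcmvpa_session")) s$subject_id else "subj",
                   character(1)),
                 n_voxels = V),
            class = "fcmvpa_scores")
}

#' @export
print.fcmvpa_scores <- function(x, ...) {
  cat(sprintf("fcmvpa eigenpattern scores: %d subjects x %d components x %d voxels\n",
              dim(x$scores)[1], x$k, x$n_voxels))
  invisible(x)
}

#' Cumulative explained-covariance map
#'
#' Per-voxel sum of the explained-covariance fractions over a component
#' range: the share of total intersubject covariance `trace(R(x) R'(x))`
#' captured by those eigenpatterns at each seed voxel.
#'
#' @param scores an `fcmvpa_scores` object (or an `fcmvpa_eigenbasis`).
#' @param components integer vector of component indices (default `1`).
#' @return numeric vector over voxels (or a scalar for a single basis).
#' @export
explained_covariance_map <- function(scores, components = 1L) {
  if (length(components) < 1) stop("empty component range")
  if (inherits(scores, "fcmvpa_eigenbasis")) {
    stopifnot(max(components) <= length(scores$xi_full))
    return(sum(scores$xi_full[components]))
  }
  stopifnot(inherits(scores, "fcmvpa_scores"),
            max(components) <= nrow(scores$xi))
  colSums(scores$xi[components, , drop = FALSE])
}

#' Reconstruct eigenpatterns from scores
#'
#' Materialises the eigenpatterns for a voxel or small region `omega` from
#' the stored scores, avoiding any need to keep whole-brain patterns for
#' every seed: `P(omega)` is proportional to the accumulation of
#' `r_n'(x) s_n(x)` over subjects and over the voxels of `omega`. For a
#' singleton region this reproduces the [voxel_svd()] patterns up to
#' per-component scale; columns are returned unit-normalised.
#'
#' @param sessions list of [bold_session()].
#' @param scores `fcmvpa_scores` from [efficient_scores()].
#' @param omega integer vector of in-mask voxel indices (nonempty).
#' @return voxels x k matrix of unit-norm pattern columns.
#' @export
reconstruct_patterns <- function(sessions, scores, omega) {
  stopifnot(length(omega) >= 1)
  V <- scores$n_voxels
  if (any(omega < 1 | omega > V)) stop("region omega lies outside the mask")
  acc <- matrix(0, V, scores$k)
  for (x in omega) {
    R <- stack_rows(sessions, x)          # N x V
    acc <- acc + crossprod(R, scores$scores[, , x])
  }
  nrm <- sqrt(colSums(acc^2))
  nrm[nrm == 0] <- 1
  sweep(acc, 2L, nrm, "/")
}

#' Project unseen subjects onto a trained eigenpattern basis
#'
#' Computes eigenpattern scores for new subjects using a training-set basis:
#' `s_new = r_new(x) P D^{-1}`, with `P` and `D` taken from the training
#' decomposition at the same seed voxel. Projecting a training subject
#' returns its training score.
#'
#' @param new_sessions list of [bold_session()] on the same mask as training.
#' @param basis `fcmvpa_eigenbasis` from [voxel_svd()] (with `seed_index`
#'   set, or supply `x`).
#' @param x seed voxel index; defaults to `basis$seed_index`.
#' @return new-subjects x k score matrix.
#' @export
project_new_subjects <- function(new_sessions, basis, x = basis$seed_index) {
  stopifnot(inherits(basis, "fcmvpa_eigenbasis"), !is.na(x))
  if (any(basis$singular_values <= 0))
    stop("retained components include a zero singular value; cannot project")
  Rnew <- stack_rows(new_sessions, x)
  Rnew %*% t(basis$patterns) %*% diag(1 / basis$singular_values,
                                      nrow = basis$k)
}

#' Concatenative group-PCA baseline
#'
#' A single global k-dimensional spatial basis obtained by temporal
#' concatenation of all subjects' normalised timeseries followed by SVD (the
#' usual group-PCA reduction), plus, per seed voxel, the cumulative fraction
#' of that voxel's intersubject connectivity covariance
#' `trace(R(x) R'(x))` captured inside the fixed basis. Because the
#' fc-MVPA basis maximises captured covariance separately at every voxel,
#' its cumulative explained fraction is always at least as large as this
#' baseline's at every voxel and every k.
#'
#' @param sessions list of [bold_session()].
#' @param k number of global components.
#' @return list with `components` (voxels x k, orthonormal) and `explained`
#'   (k x voxels matrix of cumulative captured-covariance fractions).
#' @export
pca_baseline <- function(sessions, k) {
  stopifnot(length(sessions) >= 2)
  Z <- lapply(sessions, normalize_timeseries)
  Zbig <- do.call(rbind, Z)
  sv <- svd(Zbig, nu = 0, nv = min(k, min(dim(Zbig))))
  if (ncol(sv$v) < k)
    stop(sprintf("requested k = %d exceeds achievable rank %d", k, ncol(sv$v)))
  Vk <- sv$v[, seq_len(k), drop = FALSE]
  Vvox <- ncol(Zbig)
  expl <- matrix(NA_real_, k, Vvox)
  for (x in seq_len(Vvox)) {
    R <- stack_rows(sessions, x)
    tot <- sum(R^2)
    proj <- R %*% Vk                       # N x k
    expl[, x] <- cumsum(colSums(proj^2)) / tot
  }
  list(components = Vk, explained = expl)
}
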