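#' Normalise BOLD timeseries for correlation computation
#'
#' Centres each voxel's timeseries and scales it to unit Euclidean norm, so
#' that dot products of normalised columns equal Pearson correlation
#' coefficients. Zero-variance (degenerate) voxels are set to zero and their
#' indices recorded in the `"degenerate"` attribute; they are excluded from
#' any downstream analysis.
#'
#' @param session an [bold_session()] or a plain timepoints x voxels matrix.
#' @return matrix of the same shape with normalised columns and attribute
#'   `degenerate` (integer indices of flagged voxels).
#' @export
normalize_timeseries <- function(session) {
  x <- if (inherits(session, "fcmvpa_session")) session$data else as.matrix(session)
  stopifnot(nrow(x) >= 2)
  x <- sweep(x, 2L, colMeans(x), "-")
  nrm <- sqrt(colSums(x^2))
  degenerate <- which(nrm <= .Machine$double.eps^0.5 * nrow(x))
  nrm[degenerate] <- 1
  x <- sweep(x, 2L, nrm, "/")
  if (length(degenerate)) x[, degenerate] <- 0
  attr(x, "degenerate") <- as.integer(degenerate)
  x
}

#' Seed-voxel connectivity row
#'
#' One subject's map of Pearson correlations between a seed voxel and every
#' voxel: entry `y` is `cor(data[, x], data[, y])`.
#'
#' @param normalized output of [normalize_timeseries()].
#' @param x seed voxel index.
#' @return numeric vector of length `n_voxels` with attribute `seed_index`;
#'   degenerate target voxels get 0.
#' @export
seed_row <- function(normalized, x) {
  stopifnot(x >= 1, x <= ncol(normalized))
  if (x %in% attr(normalized, "degenerate"))
    stop(sprintf("seed voxel %d is degenerate (zero variance)", x))
  v <- drop(crossprod(normalized[, x], normalized))
  attr(v, "seed_index") <- as.integer(x)
  v
}

#' Stacked connectivity matrix R(x) for a seed voxel
#'
#' Concatenates every subject's seed connectivity row into the
#' subjects-by-voxels matrix whose singular value decomposition yields the
#' seed's eigenpatterns. Rows follow the order of `sessions`; row names are
#' the subject ids.
#'
#' By default the seed's self-correlation (always 1) is retained, preserving
#' the matrix dimensions; `exclude_seed = TRUE` zeroes that column instead
#' (keeping voxel indexing intact while removing its influence on the
#' decomposition). Correlations are used raw by default; `fisher_z = TRUE`
#' applies the variance-stabilising `atanh` transform (self-correlations are
#' clamped just below 1 first), a common alternative convention.
#'
#' @param sessions list of [bold_session()] (or matrices) sharing a mask.
#' @param x seed voxel index.
#' @param exclude_seed zero out the seed's own column.
#' @param fisher_z apply the Fisher z transform to the correlations.
#' @return numeric matrix, subjects x voxels.
#' @export
stack_rows <- function(sessions, x, exclude_seed = FALSE, fisher_z = FALSE) {
  stopifnot(length(sessions) >= 2)
  masks <- lapply(sessions, function(s)
    if (inherits(s, "fcmvpa_session")) s$mask else rep(TRUE, ncol(as.matrix(s))))
  if (!all(vapply(masks, identical, logical(1), masks[[1]])))
    stop("sessions do not share a common mask")
  rows <- lapply(sessions, function(s) seed_row(normalize_timeseries(s), x))
  R <- do.call(rbind, rows)
  if (fisher_z) R <- atanh(pmin(pmax(R, -1 + 1e-7), 1 - 1e-7))
  if (exclude_seed) R[, x] <- 0
  rownames(R) <- vapply(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    if (inherits(s, "fcmvpa_session")) s$subject_id else sprintf("subj%03d", i)
  }, character(1))
  attr(R, "seed_index") <- as.integer(x)
  R
}
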