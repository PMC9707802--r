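#' Label connected suprathreshold clusters
#'
#' Connected components of a logical map. On the default 1-D voxel line,
#' neighbours are the left/right voxels (maximal runs). For volumetric data,
#' supply integer grid coordinates per voxel and a connectivity scheme
#' (18-connectivity -- faces and edges -- by default, as is conventional for
#' cluster-level fMRI inference).
#'
#' @param above logical vector over voxels.
#' @param coords optional voxels x 3 integer matrix of grid coordinates.
#' @param connectivity 6, 18 or 26 (volumetric only).
#' @return integer vector of cluster labels (0 = below threshold), labels
#'   ordered by first voxel occurrence; deterministic given the map.
#' @export
label_clusters <- function(above, coords = NULL, connectivity = 18) {
  above <- as.logical(above)
  lab <- integer(length(above))
  if (is.null(coords)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    id <- 0L
    for (i in seq_along(r$values)) if (r$values[i]) {
      id <- id + 1L
      lab[starts[i]:ends[i]] <- id
    }
    return(lab)
  }
  stopifnot(nrow(coords) == length(above), connectivity %in% c(6, 18, 26))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(offs))
  offs <- offs[nz > 0 & nz <= switch(as.character(connectivity),
                                     "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  idx <- new.env(hash = TRUE, parent = emptyenv())
  on_idx <- which(above)
  for (i in on_idx) assign(key(coords[i, , drop = FALSE]), i, envir = idx)
  id <- 0L
  for (i in on_idx) {
    if (lab[i] != 0L) next
    id <- id + 1L
    queue <- i
    lab[i] <- id
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- sweep(offs, 2L, as.numeric(coords[v, ]), "+")
      for (kk in key(nb)) {
        j <- idx[[kk]]
        if (!is.null(j) && lab[j] == 0L) { lab[j] <- id; queue <- c(queue, j) }
      }
    }
  }
  lab
}

#' Threshold-free cluster enhancement
#'
#' Integrates cluster support over all thresholds instead of fixing a single
#' cluster-forming one: each voxel accumulates
#' `extent(cluster containing it at height h)^E * h^H * dh` over the
#' threshold ladder `h = dh, 2 dh, ...`. Defaults follow the convention used
#' for multivariate connectivity maps, `H = 1`, `E = 0.5` (note that
#' activation studies more commonly use `H = 2`; both are exposed).
#' Nonpositive input voxels map to zero.
#'
#' @param stat numeric statistic map (e.g. voxelwise F).
#' @param H height exponent.
#' @param E extent exponent.
#' @param dh integration step; default `max(stat) / 100`.
#' @param coords,connectivity passed to [label_clusters()].
#' @return numeric enhanced map of the same length.
#' @export
tfce_transform <- function(stat, H = 1, E = 0.5, dh = NULL, coords = NULL,
                           connectivity = 18) {
  stopifnot(all(is.finite(stat)))
  out <- numeric(length(stat))
  top <- max(stat)
  if (top <= 0) return(out)
  dh <- dh %||% (top / 100)
  stopifnot(dh > 0)
  if (top < dh) return(out)
  for (h in seq(dh, top, by = dh)) {
    lab <- label_clusters(stat >= h, coords = coords,
                          connectivity = connectivity)
    if (!any(lab > 0L)) next
    ext <- tabulate(lab)
    on <- lab > 0L
    out[on] <- out[on] + ext[lab[on]]^E * h^H * dh
  }
  out
}

# Freedman-Lane decomposition: reduced design spanning the contrast's null
# space, plus hat/residual projectors for permutation of reduced-model
# residuals (exchangeable under the tested null even with nuisance terms)
.freedman_lane <- function(G, C) {
  sv <- svd(C, nu = 0, nv = ncol(C))
  r <- mat_rank(C)
  Nc <- if (r < ncol(C)) sv$v[, (r + 1):ncol(C), drop = FALSE] else NULL
  G0 <- if (is.null(Nc)) NULL else G %*% Nc
  N <- nrow(G)
  if (is.null(G0) || mat_rank(G0) == 0) {
    list(hat = matrix(0, N, N), res = diag(N))
  } else {
    Hm <- G0 %*% pinv(G0)
    list(hat = Hm, res = diag(N) - Hm)
  }
}

#' Permutation familywise-error inference on the statistic map
#'
#' Controls the familywise error of cluster-level claims over the voxelwise
#' multivariate statistic map by permutation: the maximum cluster statistic
#' (TFCE peak, or suprathreshold cluster mass) is recorded for each of
#' `n_perm` relabelled datasets, and each observed cluster's corrected
#' p-value is `(1 + #{permutation max >= observed}) / (n_perm + 1)` (the
#' observed labelling counts as one member of the null set, so the smallest
#' attainable p is `1 / (n_perm + 1)`).
#'
#' Relabelling uses Freedman-Lane residual permutation: scores are
#' residualised against the reduced design spanning the contrast's null
#' space (for a pure group comparison this is the intercept, and the scheme
#' reduces to ordinary label permutation), the residuals are permuted and
#' the reduced fit added back, and the full-model Wilks map is recomputed.
#'
#' In `"tfce"` mode no cluster-forming threshold is needed; significant
#' clusters are the connected components of voxels whose TFCE value reaches
#' the `alpha` FWE level. In `"cluster-mass"` mode clusters are formed at
#' the voxelwise `cluster_forming_p` uncorrected threshold and summarised by
#' the sum of F values over the cluster.
#'
#' @param scores `fcmvpa_scores` from [efficient_scores()].
#' @param design an `fcmvpa_design`.
#' @param statistic `"tfce"` (default) or `"cluster-mass"`.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the permutation stream.
#' @param alpha FWE level used to report significant clusters.
#' @param cluster_forming_p voxelwise uncorrected threshold (mass mode).
#' @param H,E,dh TFCE parameters, see [tfce_transform()].
#' @param coords,connectivity adjacency, see [label_clusters()].
#' @return object of class `fcmvpa_clusters`: `cluster_table` (data frame:
#'   label, size, peak voxel, statistic, FWE p), `clusters` (list of voxel
#'   index vectors), `voxel_p_fwe`, `tfce` (TFCE mode), `F_map`, `max_null`
#'   (permutation distribution of the max statistic), `n_perm`, `statistic`.
#' @export
permutation_fwe <- function(scores, design, statistic = c("tfce", "cluster-mass"),
                            n_perm = 1000, seed = 1L, alpha = 0.05,
                            cluster_forming_p = 0.001, H = 1, E = 0.5,
                            dh = NULL, coords = NULL, connectivity = 18) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(scores, "fcmvpa_scores"), n_perm >= 100)
  N <- dim(scores$scores)[1]; k <- scores$k; V <- scores$n_voxels
  b <- N - mat_rank(design$G)
  if (k >= b) stop("k >= error dof: cannot run the Wilks map")
  obs <- cpp_wilks_map(scores$scores, design$G, design$C)
  Fmap <- drop(obs$F)
  f_thr <- qf(1 - cluster_forming_p, obs$df1, obs$df2)
  dh_use <- dh %||% (max(Fmap) / 100)
  obs_tfce <- if (statistic == "tfce")
    tfce_transform(Fmap, H = H, E = E, dh = dh_use, coords = coords,
                   connectivity = connectivity) else NULL
  fl <- .freedman_lane(design$G, design$C)
  Yflat <- matrix(aperm(scores$scores, c(1, 2, 3)), nrow = N)  # N x (k*V)
  fit0 <- fl$hat %*% Yflat
  res0 <- fl$res %*% Yflat
  max_null <- numeric(n_perm)
  set.seed(seed)
  for (m in seq_len(n_perm)) {
    pr <- sample.int(N)
    Ystar <- fit0 + res0[pr, , drop = FALSE]
    cube <- array(Ystar, c(N, k, V))
    Fp <- drop(cpp_wilks_map(cube, design$G, design$C)$F)
    max_null[m] <- if (statistic == "tfce") {
      max(tfce_transform(Fp, H = H, E = E, dh = dh_use, coords = coords,
                         connectivity = connectivity))
    } else {
      lab <- label_clusters(Fp > f_thr, coords = coords,
                            connectivity = connectivity)
      if (any(lab > 0L)) max(rowsum(Fp[lab > 0L], lab[lab > 0L])) else 0
    }
  }
  fwe_p <- function(v) (1 + vapply(v, function(s) sum(max_null >= s), 0L)) /
    (n_perm + 1)
  if (statistic == "tfce") {
    voxel_p <- fwe_p(obs_tfce)
    lab <- label_clusters(voxel_p <= alpha, coords = coords,
                          connectivity = connectivity)
    idx <- split(which(lab > 0L), lab[lab > 0L])
    tab <- do.call(rbind, lapply(seq_along(idx), function(i) {
      vv <- idx[[i]]
      data.frame(label = i, size = length(vv),
                 peak_voxel = vv[which.max(obs_tfce[vv])],
                 statistic = max(obs_tfce[vv]),
                 p_fwe = min(voxel_p[vv]))
    }))
  } else {
    lab <- label_clusters(Fmap > f_thr, coords = coords,
                          connectivity = connectivity)
    idx <- split(which(lab > 0L), lab[lab > 0L])
    voxel_p <- rep(NA_real_, V)
    tab <- do.call(rbind, lapply(seq_along(idx), function(i) {
      vv <- idx[[i]]
      mass <- sum(Fmap[vv])
      p <- fwe_p(mass)
      voxel_p[vv] <<- p
      data.frame(label = i, size = length(vv),
                 peak_voxel = vv[which.max(Fmap[vv])],
                 statistic = mass, p_fwe = p)
    }))
  }
  if (is.null(tab))
    tab <- data.frame(label = integer(), size = integer(),
                      peak_voxel = integer(), statistic = numeric(),
                      p_fwe = numeric())
  structure(list(cluster_table = tab, clusters = unname(idx),
                 voxel_p_fwe = voxel_p, tfce = obs_tfce, F_map = Fmap,
                 max_null = max_null, n_perm = n_perm, statistic = statistic,
                 alpha = alpha),
            class = "fcmvpa_clusters")
}

#' @export
print.fcmvpa_clusters <- function(x, ...) {
  cat(sprintf("fcmvpa permutation FWE (%s, %d permutations): %d cluster(s)\n",
              x$statistic, x$n_perm, nrow(x$cluster_table)))
  if (nrow(x$cluster_table)) print(x$cluster_table, row.names = FALSE)
  invisible(x)
}
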