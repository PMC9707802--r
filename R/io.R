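#' Load BOLD sessions from 4D NIfTI files
#'
#' Reads one 4D NIfTI per subject plus a 3D brain mask, checks that every
#' volume shares the mask's grid, and returns mask-flattened
#' timepoints x voxels sessions together with the voxel-index-to-coordinate
#' map needed to write results back. Voxels with non-finite or constant
#' values anywhere are handled downstream by the degeneracy flagging in
#' [normalize_timeseries()].
#'
#' @param paths character vector of 4D NIfTI file paths (one per subject).
#' @param mask_path path to a 3D NIfTI mask (nonzero = in-mask).
#' @param subject_ids identifiers; defaults to file base names.
#' @return list with `sessions` (list of [bold_session()]), `coords`
#'   (in-mask voxels x 3 integer grid coordinates, 1-based), `dim` (mask
#'   grid dimensions), `mask_array` (logical array).
#' @export
load_sessions <- function(paths, mask_path, subject_ids = NULL) {
  mask_img <- RNifti::readNifti(mask_path)
  mdim <- c(dim(mask_img), 1L, 1L)[1:3]   # trailing singleton axes may drop
  mask <- array(as.logical(mask_img != 0), dim = mdim)
  if (!any(mask)) stop("mask contains no in-mask voxels")
  coords <- which(mask, arr.ind = TRUE)
  subject_ids <- subject_ids %||% sub("\\.nii(\\.gz)?$", "", basename(paths))
  sessions <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    img <- RNifti::readNifti(paths[i])
    d <- dim(img)
    if (length(d) != 4 || !all(d[1:3] == mdim))
      stop(sprintf("grid mismatch between %s and the mask", paths[i]))
    if (!isTRUE(all.equal(RNifti::xform(img)[1:3, 1:3],
                          RNifti::xform(mask_img)[1:3, 1:3],
                          tolerance = 1e-4)))
      stop(sprintf("affine mismatch between %s and the mask", paths[i]))
    flat <- matrix(img, prod(d[1:3]), d[4])
    dat <- t(flat[as.vector(mask), , drop = FALSE])
    # voxels with any non-finite value are zeroed: downstream normalisation
    # then flags them as degenerate and excludes them from analysis
    bad <- which(!apply(is.finite(dat), 2L, all))
    if (length(bad)) {
      warning(sprintf("%s: %d voxel(s) with non-finite values flagged degenerate",
                      basename(paths[i]), length(bad)))
      dat[, bad] <- 0
    }
    sessions[[i]] <- bold_session(dat, subject_ids[i])
  }
  list(sessions = sessions, coords = coords, dim = dim(mask),
       mask_array = mask)
}

#' Write a simulated dataset as NIfTI + design TSV
#'
#' Exports each simulated session as a 4D NIfTI (the 1-D voxel line along
#' the x axis), a matching 3D mask, and a tab-separated design table with
#' the group labels, so the file-based pipeline can be exercised end to end
#' on synthetic data. Data are stored as float32.
#'
#' @param dataset an `fcmvpa_sim`.
#' @param dir output directory (created if needed).
#' @return invisibly, a list of written paths.
#' @export
write_dataset_nifti <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  V <- ncol(dataset$sessions[[1]]$data)
  paths <- character(length(dataset$sessions))
  for (i in seq_along(dataset$sessions)) {
    dat <- dataset$sessions[[i]]$data
    arr <- array(t(dat), dim = c(V, 1, 1, nrow(dat)))
    paths[i] <- file.path(dir, sprintf("%s.nii.gz",
                                       dataset$sessions[[i]]$subject_id))
    RNifti::writeNifti(RNifti::asNifti(arr, datatype = "float"), paths[i])
  }
  mask_path <- file.path(dir, "mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(1L, c(V, 1, 1))), mask_path)
  design_path <- file.path(dir, "design.tsv")
  write.table(data.frame(subject = vapply(dataset$sessions,
                                          `[[`, "", "subject_id"),
                         group = dataset$group_labels),
              design_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(sessions = paths, mask = mask_path, design = design_path))
}

#' Write eigenpattern score volumes as NIfTI
#'
#' One 3D volume per subject and component (the storage scheme that lets
#' score maps be shared across group-level analyses), projected back into
#' the mask grid.
#'
#' @param scores `fcmvpa_scores` from [efficient_scores()].
#' @param geometry list with `dim` and `mask_array` from [load_sessions()].
#' @param dir output directory.
#' @return invisibly, the written paths (subject-major order).
#' @export
write_scores_nifti <- function(scores, geometry, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  N <- dim(scores$scores)[1]
  paths <- character(0)
  for (n in seq_len(N)) for (j in seq_len(scores$k)) {
    arr <- array(0, geometry$dim)
    arr[geometry$mask_array] <- scores$scores[n, j, ]
    p <- file.path(dir, sprintf("scores_%s_comp%02d.nii.gz",
                                scores$subject_ids[n], j))
    RNifti::writeNifti(RNifti::asNifti(arr, datatype = "float"), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a subjects-by-predictors design table
#'
#' Tab-separated table with a header row; the first column is the subject
#' identifier, remaining numeric columns are predictors.
#'
#' @param path TSV path.
#' @param contrast named numeric vector of predictor weights, or `NULL` to
#'   defer contrast choice.
#' @return an `fcmvpa_design` when `contrast` is given, otherwise the
#'   predictor matrix with subject ids as row names.
#' @export
read_design_tsv <- function(path, contrast = NULL) {
  tab <- read.delim(path, check.names = FALSE)
  ids <- tab[[1]]
  G <- as.matrix(tab[, -1, drop = FALSE])
  rownames(G) <- ids
  if (is.null(contrast)) return(G)
  cvec <- numeric(ncol(G))
  miss <- setdiff(names(contrast), colnames(G))
  if (length(miss)) stop("contrast names not in design: ",
                         paste(miss, collapse = ", "))
  cvec[match(names(contrast), colnames(G))] <- contrast
  design_spec(G, matrix(cvec, nrow = 1))
}

#' Write a statistic map (and -log10 p map) as 3D NIfTI
#'
#' Projects per-voxel values back into the mask grid from [load_sessions()].
#'
#' @param statmap `fcmvpa_statmap`.
#' @param geometry list with `dim` and `mask_array` from [load_sessions()].
#' @param prefix output path prefix; writes `<prefix>_F.nii.gz` and
#'   `<prefix>_logp.nii.gz`.
#' @return invisibly, the written paths.
#' @export
write_statmap_nifti <- function(statmap, geometry, prefix) {
  put <- function(values, path) {
    arr <- array(0, geometry$dim)
    arr[geometry$mask_array] <- values
    RNifti::writeNifti(RNifti::asNifti(arr, datatype = "float"), path)
    path
  }
  p1 <- put(statmap$F, paste0(prefix, "_F.nii.gz"))
  p2 <- put(-log10(pmax(statmap$p, .Machine$double.xmin)),
            paste0(prefix, "_logp.nii.gz"))
  invisible(c(p1, p2))
}
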