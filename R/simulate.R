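#' Simulation configuration
#'
#' Describes one synthetic BOLD study: `n_subjects` sessions of
#' `n_timepoints` x `n_voxels` data laid out on a one-dimensional voxel line.
#' Each voxel's timeseries is white Gaussian noise smoothed along the voxel
#' axis with a Gaussian kernel of width `noise_fwhm` (in voxel units) and
#' rescaled to unit marginal variance, so that changing the smoothing width
#' changes the spatial autocorrelation of the noise but not its amplitude.
#' A fraction `signal_subject_fraction` of the subjects additionally carry a
#' shared signal: one independent unit-variance Gaussian timeseries per
#' subject, multiplied by `signal_weight` and added identically to every
#' voxel of one contiguous run covering `signal_fraction` of the voxel line.
#' The two resulting subject groups (signal-carrying vs noise-only) are the
#' groups compared by the downstream connectivity tests.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param n_timepoints number of timepoints per session (>= 2).
#' @param n_voxels number of voxels on the 1-D voxel line (>= 2).
#' @param noise_fwhm full width at half maximum of the spatial smoothing
#'   kernel, in voxels; 0 disables smoothing.
#' @param signal_fraction fraction of voxels forming the contiguous signal
#'   run, in `[0, 1]`.
#' @param signal_subject_fraction fraction of subjects carrying the signal.
#' @param signal_weight amplitude of the signal relative to the unit-variance
#'   noise; 1 gives an equal-variance mixture, 0 a pure null dataset.
#' @param rng_seed integer seed making the dataset reproducible.
#' @return an object of class `fcmvpa_sim_config`.
#' @seealso [simulate_dataset()]
#' @export
sim_config <- function(n_subjects = 50, n_timepoints = 50, n_voxels = 1000,
                       noise_fwhm = 10, signal_fraction = 0.10,
                       signal_subject_fraction = 0.5, signal_weight = 1.0,
                       rng_seed = 1L) {
  stopifnot(n_subjects >= 2, n_timepoints >= 2, n_voxels >= 2,
            noise_fwhm >= 0,
            signal_fraction >= 0, signal_fraction <= 1,
            signal_subject_fraction >= 0, signal_subject_fraction <= 1,
            is.finite(signal_weight))
  structure(list(n_subjects = as.integer(n_subjects),
                 n_timepoints = as.integer(n_timepoints),
                 n_voxels = as.integer(n_voxels),
                 noise_fwhm = noise_fwhm,
                 signal_fraction = signal_fraction,
                 signal_subject_fraction = signal_subject_fraction,
                 signal_weight = signal_weight,
                 rng_seed = as.integer(rng_seed)),
            class = "fcmvpa_sim_config")
}

#' Gaussian smoothing kernel for the voxel axis
#'
#' Discrete Gaussian kernel with standard deviation
#' `fwhm / (2 * sqrt(2 * log(2)))`, truncated at four standard deviations and
#' normalised to unit sum. `fwhm = 0` returns the identity (single-tap)
#' kernel.
#'
#' @param fwhm full width at half maximum in voxel units.
#' @return numeric vector of odd length.
#' @export
gaussian_kernel <- function(fwhm) {
  if (fwhm <= 0) return(1)
  sdv <- fwhm / (2 * sqrt(2 * log(2)))
  hw <- max(1L, ceiling(4 * sdv))
  k <- exp(-0.5 * ((-hw:hw) / sdv)^2)
  k / sum(k)
}

#' One subject's BOLD session
#'
#' A light container for a timepoints-by-voxels data matrix with a subject
#' identifier and an optional in-analysis voxel mask (all-true when omitted).
#'
#' @param data numeric matrix, timepoints x voxels (>= 2 timepoints).
#' @param subject_id identifier.
#' @param mask logical per-voxel vector; defaults to all `TRUE`.
#' @return object of class `fcmvpa_session`.
#' @export
bold_session <- function(data, subject_id = "subj", mask = NULL) {
  data <- as.matrix(data)
  stopifnot(nrow(data) >= 2)
  if (is.null(mask)) mask <- rep(TRUE, ncol(data))
  stopifnot(length(mask) == ncol(data))
  structure(list(data = data, subject_id = as.character(subject_id),
                 mask = as.logical(mask)),
            class = "fcmvpa_session")
}

#' Simulate a synthetic BOLD study
#'
#' Generates the dataset described by a [sim_config()]: per subject,
#' independent Gaussian noise per timepoint and voxel, convolved along the
#' voxel axis with a Gaussian kernel (zero-padded boundaries) and rescaled to
#' exact unit marginal variance; signal-group subjects additionally receive
#' `signal_weight` times a per-subject Gaussian timeseries, added identically
#' to every voxel of the contiguous signal run. The signal run occupies the
#' first `round(signal_fraction * n_voxels)` voxels; the designated probe
#' voxels are the centre of the run (signal probe) and the voxel maximally
#' distant from the run (null probe), so that smoothing leakage cannot reach
#' the null probe.
#'
#' All randomness comes from R's RNG seeded with `config$rng_seed`, so equal
#' seeds give bit-identical datasets.
#'
#' @param config an `fcmvpa_sim_config`.
#' @return object of class `fcmvpa_sim`: a list with `sessions` (list of
#'   [bold_session()]), `group_labels` (0 = noise-only, 1 = signal),
#'   `signal_mask` (logical per voxel), `probe_voxels` (named indices
#'   `signal` and `null`) and `config`.
#' @examples
#' ds <- simulate_dataset(sim_config(n_subjects = 6, n_timepoints = 20,
#'                                   n_voxels = 50, noise_fwhm = 4))
#' sum(ds$signal_mask)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "fcmvpa_sim_config"))
  N <- config$n_subjects; Tt <- config$n_timepoints; V <- config$n_voxels
  n_sig_vox <- round(config$signal_fraction * V)
  if (config$signal_fraction > 0 && n_sig_vox < 1)
    stop("degenerate signal: signal_fraction * n_voxels < 1")
  n_sig_sub <- round(config$signal_subject_fraction * N)
  kern <- gaussian_kernel(config$noise_fwhm)
  group_labels <- rep(c(0L, 1L), c(N - n_sig_sub, n_sig_sub))
  signal_mask <- seq_len(V) <= n_sig_vox
  set.seed(config$rng_seed)
  sessions <- vector("list", N)
  noise <- lapply(seq_len(N), function(n)
    matrix(rnorm(Tt * V), Tt, V))
  for (n in seq_len(N)) {
    dat <- cpp_smooth_voxels(noise[[n]], kern)
    if (group_labels[n] == 1L && config$signal_weight != 0 && n_sig_vox >= 1) {
      s <- rnorm(Tt)
      dat[, seq_len(n_sig_vox)] <- dat[, seq_len(n_sig_vox)] +
        config$signal_weight * s
    }
    sessions[[n]] <- bold_session(dat, sprintf("sim%03d", n))
  }
  probe_signal <- if (n_sig_vox >= 1) max(1L, ceiling(n_sig_vox / 2)) else NA_integer_
  structure(list(sessions = sessions, group_labels = group_labels,
                 signal_mask = signal_mask,
                 probe_voxels = c(signal = probe_signal, null = V),
                 config = config),
            class = "fcmvpa_sim")
}

#' Two-group design matrix and contrast
#'
#' Builds the subjects-by-2 indicator design (one column per group) and the
#' one-row between-groups contrast used throughout the simulation study.
#'
#' @param group_labels vector of 0/1 group labels.
#' @param contrast length-2 contrast over the two group means.
#' @return a [design_spec()].
#' @export
design_from_groups <- function(group_labels, contrast = c(-1, 1)) {
  g <- as.integer(group_labels)
  stopifnot(all(g %in% c(0L, 1L)))
  G <- cbind(group0 = as.numeric(g == 0L), group1 = as.numeric(g == 1L))
  design_spec(G, matrix(contrast, nrow = 1))
}

#' Tiny deterministic fixture dataset
#'
#' A 6-subject, 8-timepoint, 12-voxel dataset with hand-checkable structure,
#' used throughout the unit tests: voxel 11 duplicates voxel 3 (correlation
#' exactly 1 for every subject) and voxel 12 is the negation of voxel 5
#' (correlation exactly -1). Subjects 4-6 carry a weak shared component on
#' voxels 1-4 so that group contrasts have signal to find. Fully
#' deterministic: repeated calls return identical data.
#'
#' @return an object of class `fcmvpa_sim` (same shape as
#'   [simulate_dataset()] output).
#' @export
fixture_tiny <- function() {
  N <- 6L; Tt <- 8L; V <- 12L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(20260915)
  sessions <- vector("list", N)
  group_labels <- rep(c(0L, 1L), each = 3L)
  for (n in seq_len(N)) {
    dat <- matrix(rnorm(Tt * V), Tt, V)
    if (group_labels[n] == 1L) {
      s <- rnorm(Tt)
      dat[, 1:4] <- dat[, 1:4] + 0.8 * s
    }
    dat[, 11] <- dat[, 3]
    dat[, 12] <- -dat[, 5]
    sessions[[n]] <- bold_session(dat, sprintf("fix%02d", n))
  }
  structure(list(sessions = sessions, group_labels = group_labels,
                 signal_mask = seq_len(V) <= 4L,
                 probe_voxels = c(signal = 2L, null = 9L),
                 config = NULL),
            class = "fcmvpa_sim")
}

#' @export
print.fcmvpa_sim <- function(x, ...) {
  d <- dim(x$sessions[[1]]$data)
  cat(sprintf("fcmvpa simulated dataset: %d subjects, %d timepoints, %d voxels\n",
              length(x$sessions), d[1], d[2]))
  cat(sprintf("  signal voxels: %d; signal subjects: %d; probes: signal=%s null=%s\n",
              sum(x$signal_mask), sum(x$group_labels == 1),
              x$probe_voxels[["signal"]], x$probe_voxels[["null"]]))
  invisible(x)
}
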