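#' Monte Carlo p-values at the probe voxels
#'
#' The engine behind the validity and sensitivity studies: simulates
#' `n_reps` independent datasets under a [sim_config()], and for each
#' replicate evaluates the two-group eigenpattern test at the two probe
#' voxels (signal-run centre and maximally distant null voxel) for every
#' requested number of eigenpatterns `k`. Identical in distribution to
#' running [simulate_dataset()], [efficient_scores()] and [mvpa_statmap()]
#' per replicate (the compiled path is equivalence-tested against those
#' functions), but fast enough for 10,000-replicate studies.
#'
#' @param config an `fcmvpa_sim_config`; its `rng_seed` seeds the run unless
#'   `seed` is given.
#' @param k_grid integer vector of eigenpattern counts; all must stay below
#'   `N - 2` (the two-group error dof).
#' @param n_reps number of replicates.
#' @param seed optional integer overriding `config$rng_seed`.
#' @return numeric array `n_reps x 2 x length(k_grid)` of uncorrected
#'   p-values; probe dimension named `signal`, `null`.
#' @export
monte_carlo_pvalues <- function(config, k_grid, n_reps, seed = NULL) {
  stopifnot(inherits(config, "fcmvpa_sim_config"))
  N <- config$n_subjects
  b <- N - 2L
  k_grid <- as.integer(k_grid)
  if (any(k_grid >= b))
    stop(sprintf("k values must stay below the error dof b = %d", b))
  n_sig_vox <- round(config$signal_fraction * config$n_voxels)
  if (n_sig_vox < 1) stop("degenerate signal: signal_fraction * n_voxels < 1")
  n_sig_sub <- round(config$signal_subject_fraction * N)
  group <- rep(c(0L, 1L), c(N - n_sig_sub, n_sig_sub))
  des <- design_from_groups(group)
  probe_signal <- max(1L, ceiling(n_sig_vox / 2))
  probes0 <- c(probe_signal, config$n_voxels) - 1L   # 0-based
  p <- cpp_mc_run(n_reps, N, config$n_timepoints, config$n_voxels,
                  gaussian_kernel(config$noise_fwhm),
                  0L, n_sig_vox - 1L,
                  which(group == 1L) - 1L,
                  config$signal_weight, probes0, k_grid,
                  des$G, des$C,
                  as.double(seed %||% config$rng_seed))
  dimnames(p) <- list(NULL, c("signal", "null"), paste0("k", k_grid))
  p
}

# drop k values at or beyond the error dof (the breakdown point of the
# likelihood ratio test), warning about what was skipped
.clip_k_grid <- function(k_grid, config) {
  b <- config$n_subjects - 2L
  bad <- k_grid >= b
  if (any(bad)) {
    warning(sprintf("skipping k >= error dof (%d): %s", b,
                    paste(k_grid[bad], collapse = ", ")))
    k_grid <- k_grid[!bad]
    if (!length(k_grid)) stop("no usable k values below the error dof")
  }
  k_grid
}

.roc_table <- function(p_probe, k_grid, alpha_grid, condition) {
  do.call(rbind, lapply(seq_along(k_grid), function(j) {
    data.frame(condition = condition, k = k_grid[j], alpha = alpha_grid,
               rate = vapply(alpha_grid,
                             function(a) mean(p_probe[, j] < a), 0),
               n_reps = nrow(p_probe))
  }))
}

#' Empirical false-positive rates at the null probe voxel
#'
#' Runs the Monte Carlo null study: replicate datasets, eigenpattern test at
#' the null probe voxel, and the fraction of replicates rejected at each
#' nominal level. A valid test keeps each empirical rate at its nominal
#' alpha (up to binomial Monte Carlo error).
#'
#' @inheritParams monte_carlo_pvalues
#' @param alpha_grid nominal voxel-level thresholds.
#' @param condition label stored in the table.
#' @return list: `table` (data frame with condition, k, alpha, empirical
#'   rate, replicate count), `pvalues` (raw p-value array, so any further
#'   alpha can be evaluated without re-simulation), `config`.
#' @export
run_validity <- function(config = sim_config(), k_grid = c(1, 5, 10, 20, 40),
                         alpha_grid = c(0.001, 0.002, 0.005, 0.01, 0.02,
                                        0.05, 0.1, 0.2, 0.5),
                         n_reps = 10000, seed = NULL,
                         condition = "reference") {
  k_grid <- .clip_k_grid(k_grid, config)
  p <- monte_carlo_pvalues(config, k_grid, n_reps, seed)
  list(table = .roc_table(matrix(p[, "null", ], nrow = n_reps), k_grid,
                          alpha_grid, condition),
       pvalues = p, config = config)
}

#' Empirical sensitivity at the signal probe voxel
#'
#' Same Monte Carlo machinery as [run_validity()], tabulated at the probe
#' voxel inside the signal run: the fraction of replicates in which the
#' between-group difference in that voxel's connectivity pattern is
#' detected at each nominal level.
#'
#' @inheritParams run_validity
#' @return list as in [run_validity()], rates taken at the signal voxel.
#' @export
run_sensitivity <- function(config = sim_config(), k_grid = c(1, 5, 10, 20, 40),
                            alpha_grid = c(0.001, 0.002, 0.005, 0.01, 0.02,
                                           0.05, 0.1, 0.2, 0.5),
                            n_reps = 2000, seed = NULL,
                            condition = "reference") {
  k_grid <- .clip_k_grid(k_grid, config)
  p <- monte_carlo_pvalues(config, k_grid, n_reps, seed)
  list(table = .roc_table(matrix(p[, "signal", ], nrow = n_reps), k_grid,
                          alpha_grid, condition),
       pvalues = p, config = config)
}

#' Default scenario grid for the robustness study
#'
#' The reference condition plus the six variants probing spatial noise
#' autocorrelation (smoothing width 1 and 25 voxels), session length (10 and
#' 100 timepoints) and sample size (10 and 100 subjects). The low-smoothing
#' variant is generated with FWHM = 1 (a near-delta kernel with lag-1
#' autocorrelation about 0.06); an exactly unsmoothed FWHM = 0 variant is
#' also supported by [sim_config()].
#'
#' @return named list of `fcmvpa_sim_config` objects.
#' @export
scenario_configs <- function() {
  ref <- sim_config()
  list(reference = ref,
       A_fwhm1 = sim_config(noise_fwhm = 1),
       B_fwhm25 = sim_config(noise_fwhm = 25),
       C_n10 = sim_config(n_subjects = 10),
       D_n100 = sim_config(n_subjects = 100),
       E_nt10 = sim_config(n_timepoints = 10),
       F_nt100 = sim_config(n_timepoints = 100))
}

#' Validity and sensitivity across the scenario grid
#'
#' Runs the Monte Carlo study for every scenario in [scenario_configs()]
#' (or a subset), tabulating both probe voxels. `k_grid` is clipped per
#' scenario to stay below each scenario's error dof.
#'
#' @param seed integer; scenario seeds are derived from it.
#' @param n_reps replicates per scenario.
#' @param k_grid eigenpattern counts (clipped per scenario).
#' @param alpha_grid nominal thresholds.
#' @param scenarios names from [scenario_configs()] to run.
#' @return data frame with condition, probe, k, alpha, rate, n_reps.
#' @export
run_scenarios <- function(seed = 1L, n_reps = 1000,
                          k_grid = c(1, 5, 10, 20, 40),
                          alpha_grid = c(0.001, 0.01, 0.05, 0.1, 0.5),
                          scenarios = names(scenario_configs())) {
  cfgs <- scenario_configs()[scenarios]
  out <- NULL
  for (i in seq_along(cfgs)) {
    cfg <- cfgs[[i]]
    kg <- k_grid[k_grid < cfg$n_subjects - 2L]
    if (!length(kg)) {
      warning(sprintf("scenario %s: all k >= error dof, skipped", names(cfgs)[i]))
      next
    }
    p <- monte_carlo_pvalues(cfg, kg, n_reps, seed = seed + i)
    for (probe in c("signal", "null")) {
      tb <- .roc_table(matrix(p[, probe, ], nrow = n_reps), kg, alpha_grid,
                       names(cfgs)[i])
      tb$probe <- probe
      out <- rbind(out, tb)
    }
  }
  out
}
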