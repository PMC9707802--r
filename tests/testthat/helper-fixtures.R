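# shared helpers: tiny datasets and brute-force oracles built in code

# small simulated study, cheap enough for per-test regeneration
small_sim <- function(seed = 7, n_subjects = 12, n_timepoints = 16,
                      n_voxels = 60, noise_fwhm = 4, signal_weight = 1) {
  simulate_dataset(sim_config(n_subjects = n_subjects,
                              n_timepoints = n_timepoints,
                              n_voxels = n_voxels, noise_fwhm = noise_fwhm,
                              signal_weight = signal_weight, rng_seed = seed))
}

# brute-force Pearson correlation matrix oracle (textbook formula)
pearson_oracle <- function(mat) {
  V <- ncol(mat)
  out <- matrix(NA_real_, V, V)
  for (i in seq_len(V)) for (j in seq_len(V)) {
    xi <- mat[, i] - mean(mat[, i]); yj <- mat[, j] - mean(mat[, j])
    out[i, j] <- sum(xi * yj) / sqrt(sum(xi^2) * sum(yj^2))
  }
  out
}

# direct per-voxel statistic path: stack rows, SVD scores, component GLM
direct_probe_stat <- function(sessions, design, x, k) {
  basis <- voxel_svd(stack_rows(sessions, x), k = k)
  fit <- fit_ols(design$G, basis$scores)
  H <- hypothesis_sscp(fit, design$C)
  wilks_lrt_f(fit$W, H, a = k, b = fit$b, c = nrow(design$C))
}

expect_close <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)), tol)
}
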