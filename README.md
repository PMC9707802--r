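# fcmvpa

Brain-wide connectome inference at single-voxel resolution, for researchers
who want to ask "does the *pattern* of functional connectivity between any
voxel and the rest of the brain differ with group / age / behaviour?"
without paying the multiple-comparison price of testing billions of
individual connections.

## The method

For every seed voxel `x`, each subject `n` contributes a whole-brain map of
Pearson correlations `r_n(x, y)` between the seed and every other voxel.
Stacked over subjects these form the matrix `R(x)`, which is factorised by
an (uncentred) singular value decomposition

```
S(x) D(x) P'(x) = R(x)
```

The columns of `P(x)` are the seed's **eigenpatterns** — orthonormal spatial
modes of intersubject variability in connectivity with that seed — and the
rows of `S(x)` are each subject's **eigenpattern scores**, with explained
covariance fractions `ξ_i(x) = d_i² / trace(R R')`. The first `k` scores
(default `k = 10`) enter a multivariate GLM `s_n(x) = g_n B(x) + e` whose
contrast `C B(x) = 0` is tested with the Wilks' Lambda likelihood-ratio F
(Rao's approximation, `F ~ F(ac, d)`), yielding a statistic map over seed
voxels. Familywise error over the map is controlled by permutation of the
maximum TFCE (or cluster-mass) statistic, and significant clusters are
characterised by post-hoc effect-size decompositions (`h_eig`, `h_scores`,
`h_map`). An efficient computation path derives all eigenpattern scores
directly from the timeseries, linear in the number of voxels and never
materialising voxel-by-voxel matrices.

The package also contains the method's own validation machinery: a synthetic
BOLD generator with a group-confined shared signal, and Monte Carlo studies
of the voxel-level test's false-positive calibration and power across
sample sizes, session lengths and smoothing widths.

## Worked example

```r
library(fcmvpa)

ds  <- simulate_dataset(sim_config(n_subjects = 20, n_timepoints = 40,
                                   n_voxels = 200, noise_fwhm = 5,
                                   rng_seed = 42))
des <- design_from_groups(ds$group_labels)          # two groups, C = [-1 1]
sc  <- efficient_scores(ds$sessions, k = 5)         # scores at every voxel
sm  <- mvpa_statmap(sc, des)                        # Wilks-Lambda F map
sm
#> fcmvpa statistic map (wilks): 200 voxels, F(5, 14), max F = 39.47, min p = 9.10e-08
cl  <- permutation_fwe(sc, des, statistic = "tfce", n_perm = 999, seed = 1)
cl
#> fcmvpa permutation FWE (tfce, 999 permutations): 1 cluster(s)
#>  label size peak_voxel statistic p_fwe
#>      1   20          2  1891.547 0.001
```

The single significant cluster is exactly the simulated signal run (voxels
1–20): the pattern of connectivity between those voxels and the rest of the
line differs between the groups at `p_FWE = 0.001` (the smallest value
1/(M+1) attainable with 999 permutations). Effect sizes for the cluster:

```r
eff <- effect_sizes(ds$sessions, des, omega = cl$clusters[[1]], k = 5)
round(eff$h_eig, 2)
#> [1]  2.02 -7.88 -0.85 -0.47 -0.56
```

— the group contrast loads mainly on one low-order eigenpattern: the groups
differ along a dominant mode of intersubject connectivity variability at
this cluster, and `eff$h_map` maps that difference over target voxels.

Validity of the voxel-level test at desk scale:

```r
rv <- run_validity(sim_config(n_subjects = 16, n_timepoints = 12,
                              n_voxels = 80, noise_fwhm = 4),
                   k_grid = c(2, 5), alpha_grid = 0.05,
                   n_reps = 1000, seed = 7)
rv$table
#>   condition k alpha  rate n_reps
#> 1 reference 2  0.05 0.054   1000
#> 2 reference 5  0.05 0.062   1000
```

A command-line front end (`inst/cli/fcmvpa`) exposes the same pipeline as
`simulate`, `decompose`, `infer`, `effects` and `validate` subcommands over
NIfTI + TSV inputs; see `?cli_run`.

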