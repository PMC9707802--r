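---
title: "Voxel-level multivariate pattern analysis of functional connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-level multivariate pattern analysis of functional connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcmvpa)
```

## The inferential problem

Voxel-level functional connectomics asks whether the pattern of functional
connectivity between a brain location and the rest of the brain differs
across subjects in a way explained by known factors (group, age, behaviour).
A mass-univariate treatment -- one GLM per voxel pair -- faces billions of
tests and crushing multiple-comparison corrections. This package implements
the alternative: a searchlight *multivariate pattern* analysis in which, for
every seed voxel $x$, each subject contributes one whole-brain connectivity
map, and inference is performed on a low-dimensional, voxel-specific
representation of those maps.

For subject $n$, let $z_n(x)$ be the centred, unit-norm BOLD timeseries at
voxel $x$, so that $r_n(x, y) = z_n(x)^\top z_n(y)$ is the Pearson
correlation between voxels $x$ and $y$. Stacking the seed maps
$\mathbf r_n(x)$ across the $N$ subjects gives the subjects-by-voxels matrix
$R(x)$.

## Eigenpatterns and eigenpattern scores

At each seed voxel the uncentred singular value decomposition

$$S(x)\, D(x)\, P^\top(x) = R(x)$$

defines the seed's *eigenpatterns* (columns of $P(x)$: orthonormal spatial
modes of intersubject variability in connectivity with that seed) and each
subject's *eigenpattern scores* (rows of $S(x)$). The fraction of the total
intersubject covariance captured by component $i$ is
$\xi_i(x) = d_i^2(x) / \operatorname{trace}(R(x) R^\top(x))$. By the
optimality of the SVD no other $k$-dimensional basis captures more covariance
at any $k$; the test suite checks this against both random subspaces and a
concatenative group-PCA baseline (`pca_baseline()`).

Two deliberate conventions:

* **No centring.** $R(x)$ is decomposed as-is rather than column-centred.
  The subject-mean connectivity map is then retained in the basis, and the
  first eigenpattern typically tracks the average connectivity with the seed
  (a property the tests verify on simulated signal voxels). A `center`
  argument exists for exploration.
* **Deterministic signs.** SVD signs are arbitrary; each component is
  flipped so that its pattern correlates nonnegatively with the subject-mean
  connectivity row (algebraically: score columns sum to a nonnegative
  value), with ties broken by the first nonzero pattern element. This makes
  runs and the two computation paths comparable.

The seed voxel's self-correlation column (always 1) is retained in $R(x)$,
preserving the matrix dimensions; it contributes only to the mean-like
leading component. Correlations are used raw; a Fisher-z transform is
deliberately not applied by default (the correlation scale is the one the
model above is written on), and preprocessing beyond normalisation is out of
scope.

### The efficient computation path

Materialising $R(x)$ for every seed is quadratic in voxels. `efficient_scores()`
instead uses the identity
$[R(x) R^\top(x)]_{nm} = z_n(x)^\top (Z_n Z_m^\top)\, z_m(x)$: the
time-by-time cross-product blocks $Z_n Z_m^\top$ are formed once, and each
seed's $N \times N$ Gram matrix is obtained by contracting them against the
seed columns, block of seeds by block of seeds (`block_size`). No
voxels-by-voxels matrix is ever formed and the cost is linear in the number
of voxels. Correctness is enforced by an equivalence test against the direct
per-voxel SVD (agreement to $10^{-6}$ up to component sign), which is the
implemented contract of this path. Peak memory is $O((NT)^2)$ for the
stacked temporal Gram matrix, which is the right trade for voxel counts far
exceeding $NT$.

## The multivariate GLM and its statistics

The scores enter a standard between-subjects multivariate GLM
$\mathbf s_n(x) = \mathbf g_n B(x) + \text{error}$, with design matrix $G$
(subjects $\times$ predictors) and null hypothesis $C B(x) = 0$. With
$W(x)$ and $H(x)$ the residual and hypothesis
sum-of-squares-and-products matrices (`fit_ols()`, `hypothesis_sscp()`),
two statistics are available:

* **Wilks' Lambda likelihood-ratio F** (`wilks_lrt_f()`), the default for
  the $k$-dimensional score model:
  $\lambda = |W| / |W + H|$, referred through Rao's approximation
  $F = \frac{d}{ac} \frac{1 - \lambda^{1/e}}{\lambda^{1/e}} \sim F_{ac,\, d}$
  with $a$ the response dimensionality, $b = N - \operatorname{rank}(G)$ the
  error degrees of freedom, $c = \operatorname{rank}(C)$,
  $e = \sqrt{(a^2c^2 - 4)/(a^2 + c^2 - 5)}$ and
  $d = (b - (a - c + 1)/2)\, e - ac/2 + 1$. When either Rao term is
  nonpositive, $e = 1$ -- the convention under which the small-dimension
  cases ($a \le 2$ or $c \le 2$) are exactly F-distributed; at
  $a = c = 1$ the statistic reduces exactly to the ordinary univariate F
  (tested). Validity requires $a < b$; the package refuses dimensionalities
  at or beyond that bound rather than returning numbers from a rank-deficient
  $W$.
* **Satterthwaite trace F** (`satterthwaite_f()`), for responses too
  high-dimensional for $W$ to be invertible (e.g. whole connectivity rows in
  `mva_statmap()`): $F = (b/c)\,\operatorname{tr}(H)/\operatorname{tr}(W)$
  on $F_{kc,\, kb}$ with effective dimensionality
  $k = \operatorname{tr}(W)^2 / \operatorname{tr}(W^2)$. Because $k$ is
  estimated from the sample $W$, whose eigenvalue spread understates the
  true dimension, this test is *conservative* in high dimensions (the suite
  measures rejection below the nominal level, approaching it as $b$ grows,
  and exact calibration in one dimension). It is an omnibus screen, not a
  calibrated p-value machine.

The choice of a between-voxels contrast $P(x)$ in `mva_statmap()` spans the
design space: a one-column $P$ on a single target voxel reproduces the
seed-based-connectivity univariate test exactly; the identity keeps all
targets (Satterthwaite); and the eigenpatterns weighted by inverse singular
values reproduce the score-based map exactly (change-of-basis invariance,
tested).

### Numerical choices

Pseudoinverses use an SVD cutoff at relative tolerance $10^{-10}$;
$\lambda$ is computed through Cholesky log-determinants rather than raw
determinants; non-estimable contrasts (singular $C (G^\top G)^- C^\top$)
raise an error rather than silently pseudo-inverting; zero-variance voxels
are flagged at normalisation, excluded, and reported with their original
indices. Computations are in double precision; NIfTI output is float32.

## Choosing k

There is no "correct" number of eigenpatterns: the test is valid for every
$k$ below $N - \operatorname{rank}(G)$, and $k$ trades sensitivity to large,
common effects (low $k$) against finer ones (high $k$). The package default
is $k = 10$, with the usual guidance of keeping a 5:1 to 20:1 ratio of
subjects to components; $k$ must be chosen a priori (or multiplicity-
corrected if explored).

## Cluster-level inference

Voxelwise maps are corrected by permutation of the maximum cluster
statistic. The default statistic is threshold-free cluster enhancement with
$H = 1$, $E = 0.5$ (the convention for these multivariate connectivity maps;
activation analyses more commonly use $H = 2$, and both exponents are
arguments), integrated on a ladder of 100 steps up to the map maximum.
Cluster-mass mode forms clusters at a voxelwise $p < .001$ threshold and
scores them by the sum of F values. Relabelling uses Freedman-Lane residual
permutation under the reduced model spanning the contrast's null space --
for a pure group comparison this is ordinary label permutation; with
nuisance covariates it permutes reduced-model residuals, the standard
scheme. Corrected p-values count the observed labelling in the null set,
$p = (1 + \#\{\text{perm max} \ge \text{obs}\}) / (M + 1)$. Adjacency is
left/right neighbours on the 1-D simulated voxel line and 18-connectivity
for volumetric data (6 and 26 available).

## Post-hoc effect sizes

For a significant region $\Omega$ and contrast row $c_j$, `effect_sizes()`
reports the departure from the null on three scales: per eigenpattern
($h_{\text{eig}} = \sum_{x \in \Omega} c_j \tilde B(x)$), per subject
($h_{\text{scores}}$, mapping each voxel's effect through its score matrix),
and per target voxel ($h_{\text{map}}$, mapping further through the
connectivity rows). The sums over $\Omega$ are plain accumulations, with a
`normalize = "mean"` option for cross-cluster comparability. As $k \to N$
the subject weights collapse to the constant GLM row
$c_j (G^\top G)^{-1} G^\top$ and $h_{\text{map}}$ equals the post-hoc
seed-based-connectivity effect map exactly (tested to $10^{-8}$); at
truncated $k$ it is the projection of that map onto the retained basis, and
approaches it monotonically in $k$. All of these are post-hoc, selection-
biased estimates for interpretation -- the package deliberately attaches no
p-values to them, and a `split_sessions` argument supports the
cross-validated variant (region from one half, effects from the other).

## The synthetic data generator

`simulate_dataset()` reproduces the structure of the validation study's
Monte Carlo world: a 1-D line of `n_voxels` voxels; per subject,
independent Gaussian noise per timepoint and voxel, convolved along the
voxel axis with a Gaussian kernel of `noise_fwhm` voxels (standard
deviation $\text{FWHM} / 2\sqrt{2 \ln 2}$, truncated at $\pm 4$ sd,
zero-padded boundaries) and rescaled to exact unit marginal variance so
that smoothing width changes spatial autocorrelation but not amplitude; and,
for a `signal_subject_fraction` of the subjects, a per-subject Gaussian
timeseries added identically (weighted by `signal_weight`) to one contiguous
run of `signal_fraction` of the voxels. The two probe voxels used by the
validity and sensitivity studies are the centre of the signal run and the
voxel maximally distant from it (so smoothing leakage cannot contaminate
the null probe).

What this emulates: the intersubject structure that the method's statistics
actually consume -- spatially autocorrelated noise, a group-confined shared
component, exchangeable subjects. What it does not: hemodynamics,
physiological noise, motion, temporal autocorrelation, 3-D geometry, or the
heterogeneous covariance of real BOLD. Passing the Monte Carlo suite
therefore demonstrates the statistical calibration and power behaviour of
the inferential machinery under its own assumptions, not performance on any
real dataset.

**The signal mixing weight.** The amplitude of the shared signal relative
to the unit-variance noise is a free parameter of this simulation design.
The package default is `signal_weight = 1` -- an equal-variance mixture, the
most natural reading of "a mixture of noise and signal" -- and the
validity results are independent of it (under the null the weight is
irrelevant at the null probe up to a variance-heterogeneity nuisance that
the calibration results bound). Sensitivity, however, depends on it
steeply, especially in small samples: the suite verifies monotonicity of
power in the weight, and small-sample power figures should only ever be
compared at a stated weight.

**Smoothing-versus-extent geometry.** At desk scales the signal run
(`signal_fraction` of the line) can become comparable to the smoothing
kernel, in which case noise-only subjects also show strong local
correlations around the run and group separation shrinks; test
configurations therefore keep the run wide relative to the kernel whenever
power matters. One scenario ambiguity is surfaced rather than resolved: the
low-autocorrelation robustness scenario is generated with FWHM = 1 (lag-1
autocorrelation about 0.06), while an exactly unsmoothed FWHM = 0 variant is
also supported; results are reported per configuration.

## The Monte Carlo study

`run_validity()` and `run_sensitivity()` tabulate rejection rates at the
null and signal probe voxels over grids of $k$ and nominal $\alpha$,
storing the raw per-replicate p-values so any threshold can be evaluated
without re-simulation. `run_scenarios()` crosses the reference condition
(50 subjects, 50 timepoints, 1000 voxels, FWHM 10) with six variants:
smoothing 1 and 25 voxels, 10 and 100 timepoints, 10 and 100 subjects.
The replicate counts used by the shipped tests and acceptance script are
10,000 for the reference condition and 5,000 per scenario -- the same
order as the original study design -- with the reference run shared across
all thresholds and $k$ values through the stored p-values. The compiled
Monte Carlo engine (its own seeded RNG, smoothing and probe statistics) is
equivalence-tested against the R-level module composition on identical
data, and its sampler against the standard normal distribution.

## Known limitations

* Between-subjects designs only; within-subject (repeated measures)
  contrasts are not implemented.
* No Gaussian-Random-Field parametric cluster p-values and no FDR across
  clusters; permutation FWE only.
* No ICA and no spatial-basis variants beyond identity / single-target /
  eigenpatterns; the group-PCA baseline exists for comparison, not as an
  analysis path.
* The Satterthwaite omnibus test is conservative in high dimensions (see
  above); use the score-based Wilks map when calibrated voxel p-values
  matter.
* Real-data preprocessing (realignment, denoising, filtering) is upstream
  of this package.
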