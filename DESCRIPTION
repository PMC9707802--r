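Package: fcmvpa
Title: Voxel-Level Multivariate Pattern Analysis of Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Brain-wide connectome inference from functional connectivity data
    using voxel-level multivariate pattern analysis. For every seed voxel the
    subjects-by-voxels matrix of seed connectivity maps is decomposed by
    singular value decomposition into orthogonal eigenpatterns and per-subject
    eigenpattern scores; the low-dimensional scores enter a multivariate
    general linear model tested with a Wilks' Lambda likelihood-ratio F
    approximation, with threshold-free cluster enhancement and permutation
    based familywise error control over the resulting statistic maps.
    Includes an efficient timeseries-path computation of eigenpattern scores
    that never materialises voxel-by-voxel connectivity matrices, post-hoc
    effect-size decompositions for significant clusters, a synthetic BOLD
    data generator, and a Monte Carlo validity and sensitivity study of the
    voxel-level test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
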