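test_that("per-voxel SVD basis has the advertised algebraic structure", {
  # rank one: identical rows
  row <- c(0.2, -0.5, 0.8, 0.1)
  R1 <- rbind(row, row, row, row)
  b1 <- voxel_svd(R1, k = 1)
  expect_equal(b1$xi[1], 1)
  expect_equal(sum(b1$xi_full[-1]), 0)
  expect_gt(abs(cor(drop(b1$patterns), row)), 1 - 1e-10)
  # isotropy: orthogonal equal-norm rows share covariance equally
  Riso <- diag(4) * 2
  expect_equal(voxel_svd(Riso)$xi_full, rep(0.25, 4))
  # exact reconstruction at full rank; orthonormal factors
  fx <- fixture_tiny()
  R <- stack_rows(fx$sessions, 2)
  bf <- voxel_svd(R)
  expect_close(bf$scores %*% diag(bf$singular_values) %*% bf$patterns, R,
               1e-10)
  expect_close(crossprod(bf$scores), diag(bf$k), 1e-8)
  expect_close(tcrossprod(bf$patterns), diag(bf$k), 1e-8)
  expect_equal(sum(bf$xi_full), 1)
  expect_true(all(diff(bf$singular_values) <= 1e-12))
  expect_error(voxel_svd(R, k = 7), "rank")
})

test_that("rank-k truncation beats random subspaces of the same dimension", {
  fx <- fixture_tiny()
  R <- stack_rows(fx$sessions, 4)
  k <- 2
  b <- voxel_svd(R, k = k)
  err_svd <- sum((R - b$scores %*% diag(b$singular_values) %*% b$patterns)^2)
  set.seed(11)
  err_rand <- replicate(1000, {
    Q <- qr.Q(qr(matrix(rnorm(ncol(R) * k), ncol(R), k)))
    sum((R - R %*% Q %*% t(Q))^2)
  })
  expect_true(all(err_svd <= err_rand + 1e-12))
})

test_that("timeseries-path scores equal direct per-voxel SVD scores", {
  fx <- fixture_tiny()
  sc <- efficient_scores(fx$sessions, k = 3)
  for (x in seq_len(12)) {
    d <- voxel_svd(stack_rows(fx$sessions, x), k = 3)
    # identical up to per-component sign
    for (j in 1:3) {
      s1 <- sc$scores[, j, x]; s2 <- d$scores[, j]
      expect_lt(min(max(abs(s1 - s2)), max(abs(s1 + s2))), 1e-6)
    }
    expect_close(sc$singular_values[, x], d$singular_values, 1e-8)
    expect_close(sc$xi[, x], d$xi, 1e-8)
  }
  # also on a smoothed simulated dataset with block processing engaged
  ds <- small_sim(seed = 21)
  sc2 <- efficient_scores(ds$sessions, k = 4, block_size = 17L)
  for (x in c(1, 30, 60)) {
    d <- voxel_svd(stack_rows(ds$sessions, x), k = 4)
    for (j in 1:4)
      expect_lt(min(max(abs(sc2$scores[, j, x] - d$scores[, j])),
                    max(abs(sc2$scores[, j, x] + d$scores[, j]))), 1e-6)
  }
})

test_that("score computation is equivariant under subject reordering", {
  fx <- fixture_tiny()
  perm <- c(4, 2, 6, 1, 3, 5)
  sc <- efficient_scores(fx$sessions, k = 2)
  scp <- efficient_scores(fx$sessions[perm], k = 2)
  for (x in c(2, 9)) for (j in 1:2) {
    s1 <- sc$scores[perm, j, x]; s2 <- scp$scores[, j, x]
    expect_lt(min(max(abs(s1 - s2)), max(abs(s1 + s2))), 1e-8)
  }
  expect_close(sc$xi[, 5], scp$xi[, 5], 1e-10)
})

test_that("explained covariance accumulates to one and is monotone", {
  fx <- fixture_tiny()
  sc <- efficient_scores(fx$sessions, k = 6)
  expect_close(explained_covariance_map(sc, 1:6), 1, 1e-8)
  cums <- apply(sc$xi, 2, cumsum)
  expect_true(all(diff(cums[, 1]) >= -1e-12))
  expect_true(all(cums >= -1e-12 & cums <= 1 + 1e-12))
  expect_error(explained_covariance_map(sc, integer(0)), "empty")
})

test_that("reconstructed patterns match the direct decomposition", {
  fx <- fixture_tiny()
  sc <- efficient_scores(fx$sessions, k = 3)
  P <- reconstruct_patterns(fx$sessions, sc, omega = 4)
  d <- voxel_svd(stack_rows(fx$sessions, 4), k = 3)
  for (j in 1:3) {
    cs <- abs(sum(P[, j] * d$patterns[j, ]))
    expect_gt(cs, 1 - 1e-8)
  }
  # two voxels with identical connectivity structure act like either alone
  Pdup <- reconstruct_patterns(fx$sessions, sc, omega = c(3, 11))
  P3 <- reconstruct_patterns(fx$sessions, sc, omega = 3)
  for (j in 1:3) expect_gt(abs(sum(Pdup[, j] * P3[, j])), 1 - 1e-6)
  expect_error(reconstruct_patterns(fx$sessions, sc, omega = 99), "mask")
})

test_that("leading eigenpattern tracks the group-mean connectivity row", {
  ds <- small_sim(seed = 13, n_subjects = 16, signal_weight = 2)
  x <- ds$probe_voxels[["signal"]]
  R <- stack_rows(ds$sessions, x)
  b <- voxel_svd(R, k = 1)
  m <- colMeans(R)
  expect_gt(abs(sum(b$patterns[1, ] * m)) / sqrt(sum(m^2)), 0.8)
})

test_that("projection reproduces and extends the training scores", {
  fx <- fixture_tiny()
  b <- voxel_svd(stack_rows(fx$sessions, 2), k = 3)
  expect_close(project_new_subjects(fx$sessions, b, x = 2), b$scores, 1e-8)
  # global sign flip of the raw series leaves correlations, hence scores
  flipped <- lapply(fx$sessions, function(s)
    bold_session(-s$data, s$subject_id))
  expect_close(project_new_subjects(flipped, b, x = 2), b$scores, 1e-8)
})

test_that("held-out projection beats a rank-one mean baseline", {
  ds <- small_sim(seed = 17, n_subjects = 16, signal_weight = 1)
  train <- ds$sessions[1:8]; test <- ds$sessions[9:16]
  x <- 10
  b <- voxel_svd(stack_rows(train, x), k = 5)
  Rtest <- stack_rows(test, x)
  sc_new <- project_new_subjects(test, b, x = x)
  recon <- sc_new %*% diag(b$singular_values) %*% b$patterns
  err_proj <- sum((Rtest - recon)^2)
  mrow <- colMeans(stack_rows(train, x))
  coef <- drop(Rtest %*% mrow) / sum(mrow^2)
  err_mean <- sum((Rtest - outer(coef, mrow))^2)
  expect_lte(err_proj, err_mean)
})

test_that("voxelwise SVD dominates the concatenative group-PCA baseline", {
  ds <- small_sim(seed = 23, n_subjects = 10, n_voxels = 40)
  k <- 4
  sc <- efficient_scores(ds$sessions, k = k)
  pb <- pca_baseline(ds$sessions, k = k)
  cums <- apply(sc$xi, 2, cumsum)
  expect_true(all(cums - pb$explained >= -1e-10))
  # full-rank PCA captures everything, like the per-voxel decomposition
  fx <- fixture_tiny()
  pbf <- pca_baseline(fx$sessions, k = 12)
  expect_close(pbf$explained[12, ], 1, 1e-8)
  # rank-one connectivity: a single component suffices for either basis
  row <- rnorm(6)
  expect_equal(voxel_svd(rbind(row, row))$xi_full[1], 1)
})
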