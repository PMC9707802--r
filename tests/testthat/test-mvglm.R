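test_that("OLS fit matches the normal-equation oracle", {
  set.seed(4)
  G <- cbind(1, rnorm(8), rnorm(8))
  Y <- matrix(rnorm(8 * 4), 8, 4)
  fit <- fit_ols(G, Y)
  B_oracle <- solve(t(G) %*% G) %*% t(G) %*% Y
  expect_close(fit$B, B_oracle, 1e-10)
  expect_equal(fit$b, 5)
  # intercept-only design: coefficients are column means
  fit1 <- fit_ols(matrix(1, 8, 1), Y)
  expect_close(drop(fit1$B), colMeans(Y), 1e-12)
  # responses inside the design span leave zero residual SSCP
  fit0 <- fit_ols(G, G %*% matrix(rnorm(12), 3, 4))
  expect_close(fit0$W, 0, 1e-18)
  expect_error(fit_ols(diag(3), matrix(rnorm(9), 3, 3)), "degrees of freedom")
})

test_that("hypothesis SSCP reproduces scalar test algebra", {
  set.seed(5)
  y <- rnorm(10)
  # one-sample design: H = N * mean^2
  fit <- fit_ols(matrix(1, 10, 1), matrix(y, ncol = 1))
  H <- hypothesis_sscp(fit, matrix(1, 1, 1))
  expect_equal(drop(H), 10 * mean(y)^2)
  # zero contrast row
  G <- cbind(1, rnorm(10))
  fit2 <- fit_ols(G, matrix(rnorm(20), 10, 2))
  expect_equal(hypothesis_sscp(fit2, matrix(0, 1, 2)),
               matrix(0, 2, 2))
  # equal group means on a noiseless toy: H vanishes
  Gg <- cbind(rep(1:0, each = 3), rep(0:1, each = 3))
  Yg <- matrix(c(1, 2, 3, 1, 2, 3), ncol = 1)
  fitg <- fit_ols(Gg, Yg)
  Hg <- hypothesis_sscp(fitg, matrix(c(-1, 1), 1))
  expect_lt(abs(drop(Hg)), 1e-20)
})

test_that("Wilks LRT reduces exactly to the univariate F at a = c = 1", {
  set.seed(6)
  for (rep in 1:5) {
    y <- rnorm(14)
    g <- rep(0:1, 7)
    des <- design_from_groups(g)
    fit <- fit_ols(des$G, matrix(y, ncol = 1))
    H <- hypothesis_sscp(fit, des$C)
    w <- wilks_lrt_f(fit$W, H, a = 1, b = fit$b, c = 1)
    tt <- t.test(y ~ g, var.equal = TRUE)
    expect_equal(w$F, unname(tt$statistic^2), tolerance = 1e-12)
    expect_equal(w$p, tt$p.value, tolerance = 1e-12)
    expect_equal(w$df1, 1)
    expect_equal(w$df2, 12)
    m <- mua_stat(y, des)
    expect_equal(m$F, w$F, tolerance = 1e-12)
    expect_equal(m$p, w$p, tolerance = 1e-12)
  }
})

test_that("Wilks LRT handles degenerate and boundary inputs as specified", {
  W <- diag(3)
  z <- wilks_lrt_f(W, matrix(0, 3, 3), a = 3, b = 10, c = 1)
  expect_equal(z$lambda, 1)
  expect_equal(z$F, 0)
  expect_equal(z$p, 1)
  expect_error(wilks_lrt_f(W, W, a = 3, b = 3, c = 1),
               "likelihood ratio test assumptions")
  expect_error(wilks_lrt_f(matrix(0, 2, 2), diag(2), a = 2, b = 10, c = 1),
               "singular")
})

test_that("Wilks LRT is invariant to invertible response transformations", {
  set.seed(8)
  Y <- matrix(rnorm(20 * 4), 20, 4)
  des <- design_from_groups(rep(0:1, 10))
  A <- matrix(rnorm(16), 4, 4) + 4 * diag(4)
  f1 <- {
    fit <- fit_ols(des$G, Y); H <- hypothesis_sscp(fit, des$C)
    wilks_lrt_f(fit$W, H, 4, fit$b, 1)
  }
  f2 <- {
    fit <- fit_ols(des$G, Y %*% A); H <- hypothesis_sscp(fit, des$C)
    wilks_lrt_f(fit$W, H, 4, fit$b, 1)
  }
  expect_equal(f1$lambda, f2$lambda, tolerance = 1e-10)
  expect_equal(f1$F, f2$F, tolerance = 1e-8)
})

test_that("null p-values of the Wilks F are uniform across an (a, b, c) grid", {
  # simulation oracle of the F(ac, d) law: Gaussian responses under the null
  cases <- list(c(a = 5, c = 1, N = 50), c(a = 2, c = 2, N = 20),
                c(a = 10, c = 1, N = 30), c(a = 3, c = 2, N = 15))
  for (cs in cases) {
    a <- cs["a"]; cdf <- cs["c"]; N <- cs["N"]
    q <- cdf + 1  # predictors: groups/levels
    G <- matrix(0, N, q)
    lev <- rep_len(seq_len(q), N)
    G[cbind(seq_len(N), lev)] <- 1
    C <- cbind(diag(cdf), -1)
    n_draws <- if (a == 5 && N == 50) 20000 else 4000
    cube <- array(rnorm(N * a * n_draws), c(N, a, n_draws))
    p <- drop(fcmvpa:::cpp_wilks_map(cube, G, C)$p)
    expect_gt(stats::ks.test(p, punif)$p.value, 0.01)
    expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / n_draws))
  }
})

test_that("Satterthwaite trace F has the stated reductions and null level", {
  set.seed(9)
  # 1-D response: k_eff = 1, ordinary F ratio
  y <- rnorm(12)
  des <- design_from_groups(rep(0:1, 6))
  fit <- fit_ols(des$G, matrix(y, ncol = 1))
  H <- hypothesis_sscp(fit, des$C)
  s <- satterthwaite_f(fit$W, H, fit$b, 1)
  expect_equal(s$k_eff, 1)
  expect_equal(s$F, mua_stat(y, des)$F, tolerance = 1e-10)
  # W proportional to the identity: k_eff equals the dimension
  expect_equal(satterthwaite_f(3 * diag(7), diag(7), 10, 1)$k_eff, 7)
  expect_error(satterthwaite_f(matrix(0, 2, 2), diag(2), 10, 1), "tr\\(W\\)")
  # null behaviour with spherical Gaussian responses of dimension 20: the
  # trace F with estimated k_eff is valid but conservative (the sample
  # k_eff = tr(W)^2/tr(W^2) underestimates the true dimension, widening the
  # reference distribution), approaching the nominal level as b grows
  N <- 50; dims <- 20; reps <- 3000
  des2 <- design_from_groups(rep(0:1, N / 2))
  rej <- logical(reps)
  for (i in seq_len(reps)) {
    Y <- matrix(rnorm(N * dims), N, dims)
    f <- fit_ols(des2$G, Y)
    h <- hypothesis_sscp(f, des2$C)
    rej[i] <- satterthwaite_f(f$W, h, f$b, 1)$p < 0.05
  }
  expect_lt(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / reps))  # never invalid
  expect_gt(mean(rej), 0.005)
  # with the population covariance spherical and known-dimension reference
  # (k_eff exact for W proportional to I), calibration is exact in 1-D
  rej1 <- vapply(seq_len(reps), function(i) {
    y <- matrix(rnorm(N), ncol = 1)
    f <- fit_ols(des2$G, y)
    satterthwaite_f(f$W, hypothesis_sscp(f, des2$C), f$b, 1)$p < 0.05
  }, TRUE)
  expect_lt(abs(mean(rej1) - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("the voxelwise score map composes the component operations", {
  ds <- small_sim(seed = 19)
  des <- design_from_groups(ds$group_labels)
  sc <- efficient_scores(ds$sessions, k = 3)
  sm <- mvpa_statmap(sc, des)
  for (x in c(1, 25, 60)) {
    fit <- fit_ols(des$G, sc$scores[, , x])
    H <- hypothesis_sscp(fit, des$C)
    w <- wilks_lrt_f(fit$W, H, 3, fit$b, 1)
    expect_equal(sm$F[x], w$F, tolerance = 1e-10)
    expect_equal(sm$p[x], w$p, tolerance = 1e-10)
  }
  expect_error(mvpa_statmap(efficient_scores(ds$sessions, k = 11), des),
               "error dof")
})

test_that("group-label permutation leaves the null F distribution unchanged", {
  ds <- small_sim(seed = 29, signal_weight = 0)
  des <- design_from_groups(ds$group_labels)
  sc <- efficient_scores(ds$sessions, k = 3)
  f1 <- mvpa_statmap(sc, des)$F
  perm <- sample(seq_along(ds$group_labels))
  des2 <- design_from_groups(ds$group_labels[perm])
  sc2 <- sc
  sc2$scores <- sc$scores  # same data; permuted design only relabels groups
  f2 <- mvpa_statmap(sc2, des2)$F
  expect_gt(suppressWarnings(stats::ks.test(f1, f2)$p.value), 1e-4)
})

test_that("F grows monotonically with a pure group shift in scores", {
  set.seed(33)
  base <- matrix(rnorm(20 * 3), 20, 3)
  des <- design_from_groups(rep(0:1, each = 10))
  fs <- vapply(c(0.5, 1.5, 3), function(shift) {
    Y <- base
    Y[11:20, 1] <- Y[11:20, 1] + shift
    fit <- fit_ols(des$G, Y)
    H <- hypothesis_sscp(fit, des$C)
    wilks_lrt_f(fit$W, H, 3, fit$b, 1)$F
  }, 0)
  expect_true(all(diff(fs) > 0))
})

test_that("spatial-contrast maps reduce to their stated special cases", {
  fx <- fixture_tiny()
  des <- design_from_groups(fx$group_labels)
  # identity contrast: Satterthwaite on the full rows
  sm_id <- mva_statmap(fx$sessions, des, P = "identity", voxels = c(2, 9))
  R <- stack_rows(fx$sessions, 2)
  fit <- fit_ols(des$G, R)
  H <- hypothesis_sscp(fit, des$C)
  s <- satterthwaite_f(fit$W, H, fit$b, 1)
  expect_equal(sm_id$F[1], s$F, tolerance = 1e-10)
  expect_equal(sm_id$stat, "satterthwaite")
  # unit-vector contrast: the univariate (seed-based) test on one connection
  target <- 7
  P1 <- matrix(0, 12, 1); P1[target, 1] <- 1
  sm_sbc <- mva_statmap(fx$sessions, des, P = P1, voxels = 2)
  r_vals <- stack_rows(fx$sessions, 2)[, target]
  expect_equal(sm_sbc$F[1], mua_stat(r_vals, des)$F, tolerance = 1e-8)
  # eigenpatterns scaled by inverse singular values: exactly the score map
  k <- 3
  sc <- efficient_scores(fx$sessions, k = k)
  sm_mvpa <- mvpa_statmap(sc, des)
  Pfun <- function(x) {
    b <- voxel_svd(stack_rows(fx$sessions, x), k = k)
    t(b$patterns) %*% diag(1 / b$singular_values)
  }
  sm_eq <- mva_statmap(fx$sessions, des, P = Pfun, voxels = c(2, 9))
  expect_equal(sm_eq$F, sm_mvpa$F[c(2, 9)], tolerance = 1e-8)
  expect_equal(sm_eq$lambda, sm_mvpa$lambda[c(2, 9)], tolerance = 1e-8)
  expect_error(mva_statmap(fx$sessions, des, P = matrix(0, 12, 0), voxels = 2),
               "zero columns")
})

test_that("univariate connection test matches a hand-computed two-group t", {
  vals <- c(1.1, 0.9, 1.0, 2.1, 1.9, 2.0)
  des <- design_from_groups(rep(0:1, each = 3))
  m <- mua_stat(vals, des)
  g1 <- vals[1:3]; g2 <- vals[4:6]
  sp <- sqrt(((2) * var(g1) + (2) * var(g2)) / 4)
  t_hand <- (mean(g2) - mean(g1)) / (sp * sqrt(2 / 3))
  expect_equal(m$t, t_hand, tolerance = 1e-12)
  expect_equal(m$F, t_hand^2, tolerance = 1e-12)
  # equal groups of identical values: t = 0, p = 1
  m0 <- mua_stat(rep(c(3, 3, 3), 2), design_from_groups(rep(0:1, 3)))
  expect_equal(m0$t, 0)
  expect_equal(m0$p, 1)
})
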