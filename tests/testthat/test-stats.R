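test_that("shape PCA matches a covariance eigendecomposition and conserves variance", {
  set.seed(1)
  X <- matrix(rnorm(12 * 15), 12, 15)
  p <- shape_pca(X)
  ev <- eigen(cov(X), symmetric = TRUE)$values
  expect_equal(p$eigenvalues, ev[seq_along(p$eigenvalues)], tolerance = 1e-9)
  expect_equal(sum(p$eigenvalues), p$total_variance, tolerance = 1e-10)
  expect_equal(crossprod(p$loadings), diag(ncol(p$loadings)),
               tolerance = 1e-10, ignore_attr = TRUE)
  # one-dimensional variation: PC1 explains everything
  base <- rnorm(15); dirv <- rnorm(15)
  X1 <- outer(rnorm(10), dirv) + matrix(base, 10, 15, byrow = TRUE)
  p1 <- shape_pca(X1)
  expect_equal(p1$eigenvalues[1] / sum(p1$eigenvalues), 1, tolerance = 1e-10)
  expect_error(shape_pca(X[1:2, ]), "at least 3")
})

test_that("OLS regression: closed form, perfect fit, type-I calibration", {
  f <- ols_regress(1:4, c(2, 4, 5, 9))
  # normal equations by hand: slope 2.2, intercept -0.5
  expect_equal(f$slope, 2.2, tolerance = 1e-12)
  expect_equal(f$intercept, -0.5, tolerance = 1e-12)
  expect_equal(f$r_squared, 1 - sum((c(2, 4, 5, 9) - (2.2 * (1:4) - 0.5))^2) /
                 sum((c(2, 4, 5, 9) - 5)^2), tolerance = 1e-12)
  fp <- ols_regress(1:10, 2 * (1:10))
  expect_equal(fp$r_squared, 1, tolerance = 1e-12)
  expect_lt(fp$p_value, 1e-12)
  expect_error(ols_regress(rep(1, 5), rnorm(5)), "constant")
  set.seed(2)
  rej <- mean(replicate(2000, ols_regress(rnorm(12), rnorm(12))$p_value < 0.05))
  expect_gte(rej, 0.03); expect_lte(rej, 0.07)
})

test_that("two-block PLS: self-correlation, grid oracle, type-I calibration", {
  set.seed(3)
  a <- matrix(rnorm(12 * 5), 12, 5)
  expect_equal(two_block_pls(a, a, n_perm = 199, seed = 1)$r_pls, 1,
               tolerance = 1e-10)
  # 5x2 blocks against a dense angle-grid maximization of score covariance
  for (i in 1:3) {
    A <- matrix(rnorm(10), 5, 2); B <- matrix(rnorm(10), 5, 2)
    res <- two_block_pls(A, B, n_perm = 199, seed = 1)
    Ac <- scale(A, scale = FALSE); Bc <- scale(B, scale = FALSE)
    th <- seq(0, pi, length.out = 20000)
    best <- -Inf; best_uv <- NULL
    for (t1 in th[seq(1, 20000, by = 140)]) {
      u <- c(cos(t1), sin(t1))
      # given u, optimal v maximizes cov: v proportional to t(Bc) Ac u
      v <- crossprod(Bc, Ac %*% u); v <- v / sqrt(sum(v^2))
      cv <- abs(sum((Ac %*% u) * (Bc %*% v)))
      if (cv > best) { best <- cv; best_uv <- list(u = u, v = v) }
    }
    # refine around the best u
    f <- function(t1) {
      u <- c(cos(t1), sin(t1))
      v <- crossprod(Bc, Ac %*% u); v <- v / sqrt(sum(v^2))
      -abs(sum((Ac %*% u) * (Bc %*% v)))
    }
    op <- optimize(f, c(0, pi), tol = 1e-12)
    u <- c(cos(op$minimum), sin(op$minimum))
    ang <- acos(min(1, abs(sum(u * res$left_vectors))))
    expect_lt(ang, 1e-3)
  }
  # type-I error on independent Gaussian blocks
  set.seed(4)
  rej <- mean(replicate(300, {
    two_block_pls(matrix(rnorm(72), 12, 6), matrix(rnorm(72), 12, 6),
                  n_perm = 199, seed = sample.int(1e6, 1))$p_value < 0.05
  }))
  expect_gte(rej, 0.02); expect_lte(rej, 0.09)
  expect_warning(two_block_pls(a, a, n_perm = 50, seed = 1), "permutations")
})

test_that("CR modularity: zero cross-covariance, integrated and modular regimes", {
  set.seed(5)
  # exact zero cross-covariance (residualized blocks)
  n <- 10
  Xa <- scale(matrix(rnorm(n * 4), n, 4), scale = FALSE)
  Xb <- scale(matrix(rnorm(n * 4), n, 4), scale = FALSE)
  Xb <- Xb - Xa %*% solve(crossprod(Xa), crossprod(Xa, Xb))
  A2 <- cbind(Xa, Xa %*% matrix(rnorm(8), 4, 2))
  B2 <- cbind(Xb, Xb %*% matrix(rnorm(8), 4, 2))
  cr0 <- modularity_cr(A2, B2, n_perm = 199, seed = 1)
  expect_lt(cr0$cr, 1e-10)
  # single common factor: integrated, CR near 1, mostly non-significant
  # (columns are the permutable units here: coord_dim = 1)
  crs <- replicate(20, {
    f <- rnorm(12)
    A <- outer(f, rnorm(9)) + 0.3 * matrix(rnorm(108), 12, 9)
    B <- outer(f, rnorm(9)) + 0.3 * matrix(rnorm(108), 12, 9)
    r <- modularity_cr(A, B, n_perm = 199, seed = 7, coord_dim = 1)
    c(r$cr, r$p_value)
  })
  expect_gt(mean(crs[1, ]), 0.75)
  expect_gt(mean(crs[2, ] > 0.05), 0.7)
  # two independent factors: modular, CR < 1 and significant in most runs
  pow <- replicate(50, {
    f1 <- rnorm(12); f2 <- rnorm(12)
    A <- outer(f1, rnorm(9)) + 0.3 * matrix(rnorm(108), 12, 9)
    B <- outer(f2, rnorm(9)) + 0.3 * matrix(rnorm(108), 12, 9)
    r <- modularity_cr(A, B, n_perm = 199, seed = 7, coord_dim = 1)
    c(r$cr, r$p_value)
  })
  expect_true(all(pow[1, ] < 1))
  expect_gte(mean(pow[2, ] < 0.05), 0.9)
  expect_error(modularity_cr(matrix(rnorm(36), 12, 3),
                             matrix(rnorm(72), 12, 6)), "at least 2")
})

test_that("permutation statistics honor the p-value floor and are seed-reproducible", {
  set.seed(6)
  a <- matrix(rnorm(96), 12, 8); b <- matrix(rnorm(96), 12, 8)
  r1 <- two_block_pls(a, b, n_perm = 199, seed = 42)
  r2 <- two_block_pls(a, b, n_perm = 199, seed = 42)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$r_pls, r2$r_pls)
  expect_gte(r1$p_value, 1 / 200)
  c1 <- modularity_cr(a, b, n_perm = 199, seed = 42, coord_dim = 1)
  c2 <- modularity_cr(a, b, n_perm = 199, seed = 42, coord_dim = 1)
  expect_identical(c1$p_value, c2$p_value)
  # z near 0 when the observed statistic sits in the null
  zs <- replicate(40, two_block_pls(matrix(rnorm(60), 12, 5),
                                    matrix(rnorm(60), 12, 5),
                                    n_perm = 99,
                                    seed = sample.int(1e6, 1))$effect_size_z)
  expect_lt(abs(mean(zs)), 0.6)
})

test_that("r-PLS and CR are invariant to rigid motion of the specimens; CR to scale", {
  set.seed(7)
  pop <- generate_population(population_spec(n_specimens = 8, seed = 13,
                                             meshes = FALSE))
  ga <- gpa(pop_configs(pop))
  bl <- subset_blocks(ga, landmark_set(3))
  a <- flatten_shapes(bl$bony); b <- flatten_shapes(bl$membranous)
  r0 <- two_block_pls(a, b, n_perm = 99, seed = 1)$r_pls
  c0 <- modularity_cr(a, b, n_perm = 99, seed = 1)$cr
  # rigidly move every raw specimen: superimposition absorbs the motion, so
  # the downstream statistics are unchanged
  moved <- lapply(pop_configs(pop), function(cfg) {
    cfg$points <- cfg$points %*% random_rotation() +
      matrix(rnorm(3), nrow(cfg$points), 3, byrow = TRUE)
    cfg
  })
  ga2 <- gpa(moved)
  bl2 <- subset_blocks(ga2, landmark_set(3))
  a2 <- flatten_shapes(bl2$bony); b2 <- flatten_shapes(bl2$membranous)
  expect_equal(two_block_pls(a2, b2, n_perm = 99, seed = 1)$r_pls, r0,
               tolerance = 1e-8)
  expect_equal(modularity_cr(a2, b2, n_perm = 99, seed = 1)$cr, c0,
               tolerance = 1e-6)
  # r-PLS is also strictly invariant to a common rotation applied to every
  # landmark triple of the aligned arrays
  R <- random_rotation()
  rot <- function(M) {
    out <- M
    for (j in seq_len(ncol(M) / 3)) {
      idx <- (3 * j - 2):(3 * j)
      out[, idx] <- M[, idx] %*% R
    }
    out
  }
  expect_equal(two_block_pls(rot(a), rot(b), n_perm = 99, seed = 1)$r_pls,
               r0, tolerance = 1e-10)
  expect_equal(modularity_cr(2.7 * a, 2.7 * b, n_perm = 99, seed = 1)$cr,
               c0, tolerance = 1e-10)
})

test_that("Wilcoxon rank-sum: enumeration, symmetry, permutation agreement", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p_value, 0.1, tolerance = 1e-12)  # 2/20 extreme assignments
  expect_warning(w0 <- wilcoxon_rank_sum(rep(2, 4), rep(2, 5)), "identical")
  expect_equal(w0$p_value, 1)
  set.seed(8)
  a <- rnorm(40); b <- rnorm(45, 0.5)
  w1 <- wilcoxon_rank_sum(a, b)
  # independent permutation oracle on the rank-sum statistic (two-sided by
  # doubling the smaller tail, matching the rank-sum convention)
  pooled <- c(a, b); na <- length(a)
  robs <- sum(rank(pooled)[1:na])
  perm <- replicate(20000, sum(rank(pooled)[sample(85, na)]))
  p_perm <- min(1, 2 * min(mean(perm <= robs), mean(perm >= robs)))
  expect_lt(abs(w1$p_value - p_perm), 0.01)
})

test_that("regression battery: default has 26 models, self-regression R2 = 1", {
  pop <- generate_population(population_spec(n_specimens = 8, seed = 14,
                                             meshes = FALSE))
  ga <- gpa(lapply(pop_configs(pop), resample_config_curves))
  bat <- regression_battery(ga)
  expect_equal(nrow(bat), 26)
  expect_equal(sum(bat$statistic == "pc1"), 11)
  expect_equal(sum(bat$statistic == "log_centroid_size"), 15)
  expect_true(all(is.na(bat$error)))
  # predictor == response with log CS is an exact fit
  self <- regression_battery(ga, data.frame(
    model = "self", response = "bony_utricle", predictor = "bony_utricle",
    statistic = "log_centroid_size", stringsAsFactors = FALSE))
  expect_equal(self$r_squared, 1, tolerance = 1e-10)
  # an unresolvable subset is recorded, not fatal
  bad <- regression_battery(ga, data.frame(
    model = "bad", response = "nope", predictor = "bony_utricle",
    statistic = "pc1", stringsAsFactors = FALSE))
  expect_false(is.na(bad$error))
})
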