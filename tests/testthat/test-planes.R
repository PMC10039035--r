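test_that("triad planes: normals, order invariance, equivariance, collinearity", {
  p <- plane_from_triad(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(abs(p$normal), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(p$rms_residual, 0)
  set.seed(1)
  a <- rnorm(3); b <- rnorm(3); cc <- rnorm(3)
  p1 <- plane_from_triad(a, b, cc)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    pts <- list(a, b, cc)[perm]
    p2 <- plane_from_triad(pts[[1]], pts[[2]], pts[[3]])
    expect_equal(abs(sum(p1$normal * p2$normal)), 1, tolerance = 1e-12)
  }
  R <- random_rotation()
  p3 <- plane_from_triad(R %*% a, R %*% b, R %*% cc)
  expect_equal(abs(sum(p3$normal * (R %*% p1$normal))), 1, tolerance = 1e-12)
  expect_error(plane_from_triad(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
               "collinear")
})

test_that("surface planes: exact on coplanar clouds, matches the grid oracle", {
  set.seed(2)
  n0 <- c(1, 2, 3) / sqrt(14)
  fr <- list(e1 = c(-2, 1, 0) / sqrt(5))
  fr$e2 <- c(n0[2] * fr$e1[3] - n0[3] * fr$e1[2],
             n0[3] * fr$e1[1] - n0[1] * fr$e1[3],
             n0[1] * fr$e1[2] - n0[2] * fr$e1[1])
  flat <- t(sapply(1:60, function(i)
    runif(1, -2, 2) * fr$e1 + runif(1, -2, 2) * fr$e2))
  pf <- plane_from_surface(flat)
  expect_lt(pf$rms_residual, 1e-12)
  expect_equal(abs(sum(pf$normal * n0)), 1, tolerance = 1e-10)
  # noisy recovery within 1 degree
  noisy <- flat + matrix(rnorm(180, 0, 0.01), 60, 3)
  expect_lt(angle_between_planes(plane_from_surface(noisy)$normal, n0), 1)
  # 4-point cloud vs dense direction grid
  for (i in 1:3) {
    pts <- matrix(rnorm(12), 4, 3)
    impl <- plane_from_surface(pts)$normal
    orc <- plane_grid_oracle(pts)
    expect_lt(angle_between_planes(impl, orc), 0.1)
  }
  expect_error(plane_from_surface(cbind(1:5, 2 * (1:5), 3 * (1:5))),
               "rank-deficient")
})

test_that("plane angles: closed forms and constructed rotations", {
  expect_equal(angle_between_planes(c(0, 0, 1), c(0, 0, -1)), 0,
               tolerance = 1e-12)
  expect_equal(angle_between_planes(c(0, 0, 1), c(0, 1, 1) / sqrt(2)), 45,
               tolerance = 1e-10)
  set.seed(3)
  n0 <- c(0.2, -0.5, 0.9); n0 <- n0 / sqrt(sum(n0^2))
  inplane <- c(n0[2], -n0[1], 0); inplane <- inplane / sqrt(sum(inplane^2))
  for (th in c(5, 10, 30)) {
    n1 <- as.numeric(rotation_axis_angle(inplane, th) %*% n0)
    expect_equal(angle_between_planes(n0, n1), th, tolerance = 1e-9)
    expect_equal(angle_between_planes(n1, n0),
                 angle_between_planes(n0, n1), tolerance = 1e-12)
  }
})

test_that("maculae orientation: noiseless offsets recovered exactly", {
  for (delta in c(5, 10, 30)) {
    pop <- generate_population(population_spec(
      n_specimens = 3, seed = 4, covariance_mode = "null",
      landmark_noise_sd = 0, plane_offset_deg = delta,
      plane_offset_sd_deg = 0, meshes = FALSE))
    or <- maculae_orientation_analysis(pop_configs(pop))
    s <- or$summary
    u246 <- s$mean_deg[s$name == "u_246_triad"]
    s8910 <- s$mean_deg[s$name == "s_8910_triad"]
    expect_equal(u246, delta, tolerance = 1e-9)
    expect_equal(s8910, delta, tolerance = 1e-9)
    expect_lt(max(s$sd_deg[s$name %in% c("u_246_triad", "s_8910_triad")]),
              1e-9)
  }
})

test_that("maculae orientation: angles are invariant to specimen rigid motion", {
  pop <- generate_population(population_spec(n_specimens = 3, seed = 5,
                                             meshes = FALSE))
  cfgs <- pop_configs(pop)
  or1 <- maculae_orientation_analysis(cfgs)
  moved <- lapply(cfgs, function(cfg) {
    R <- random_rotation()
    cfg$points <- cfg$points %*% R + matrix(rnorm(3), nrow(cfg$points), 3,
                                            byrow = TRUE)
    cfg
  })
  or2 <- maculae_orientation_analysis(moved)
  expect_equal(or2$angles$angle_deg, or1$angles$angle_deg, tolerance = 1e-8)
})

test_that("built-in inter-plane angle correlation is recovered by the regression", {
  r2s <- vapply(1:8, function(s) {
    pop <- generate_population(population_spec(
      n_specimens = 12, seed = 600 + s, angle_r2 = 0.5, meshes = FALSE))
    or <- maculae_orientation_analysis(pop_configs(pop))
    or$interplane_regression$fit$r_squared
  }, numeric(1))
  expect_gt(mean(r2s), 0.30)
  expect_lt(mean(r2s), 0.70)
})

test_that("surface-based pairings use supplied macular point clouds", {
  pop <- generate_population(population_spec(n_specimens = 3, seed = 6,
                                             covariance_mode = "null",
                                             landmark_noise_sd = 0,
                                             plane_offset_sd_deg = 0,
                                             meshes = FALSE))
  cfgs <- pop_configs(pop)
  # synthesize macular "surfaces" as jittered in-plane clouds around the triads
  surfaces <- lapply(cfgs, function(cfg) {
    tri_u <- cfg$points[match(paste0("LM", 17:19), cfg$labels), ]
    tri_s <- cfg$points[match(paste0("LM", 20:22), cfg$labels), ]
    cloud <- function(tri) {
      w <- matrix(runif(150), 50, 3); w <- w / rowSums(w)
      w %*% tri
    }
    list(utricle = cloud(tri_u), saccule = cloud(tri_s),
         spherical_recess = cloud(cfg$points[match(paste0("LM", 8:10),
                                                   cfg$labels), ]))
  })
  names(surfaces) <- vapply(cfgs, function(cfg) cfg$specimen_id, character(1))
  or <- maculae_orientation_analysis(cfgs, surfaces = surfaces)
  s <- or$summary
  expect_equal(nrow(s), 8)   # all eight pairings resolvable
  tri <- s$mean_deg[s$name == "u_246_triad"]
  srf <- s$mean_deg[s$name == "u_246_surface"]
  expect_equal(tri, srf, tolerance = 1e-6)
})
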