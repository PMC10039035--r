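test_that("the real spherical-harmonic basis is orthonormal under area weights", {
  sp <- icosphere(4)
  M <- sph_basis(sp$vertices, 4)
  w <- otolithmorph:::.vertex_area_weights(sp$vertices, sp$faces)
  G <- crossprod(M * w, M)        # approximates the sphere inner product
  expect_equal(G, diag(25), tolerance = 5e-3, ignore_attr = TRUE)
})

test_that("spherical parametrization: sphere and ellipsoid valid, torus rejected", {
  sp <- icosphere(3)
  par <- spherical_parametrize(sp)
  expect_equal(par$flipped, 0)
  expect_lt(max(abs(par$directions - sp$vertices)), 1e-12)
  expect_lt(par$area_distortion, 2)
  ell <- otl_mesh(sp$vertices %*% diag(c(2, 1, 0.5)), sp$faces)
  par_e <- spherical_parametrize(ell)
  expect_equal(par_e$flipped, 0)
  expect_true(all(abs(rowSums(par_e$directions^2) - 1) < 1e-12))
  expect_error(spherical_parametrize(torus_mesh()), "topology")
})

test_that("degree-1 fit is exact for spheres; RMSE is monotone on the degree ladder", {
  sp <- icosphere(4)
  r <- 2.3
  ball <- otl_mesh(sp$vertices * r, sp$faces)
  fit <- spharm_fit(ball, degree = 1)
  expect_lt(fit$rmse, 1e-6 * r)
  pd <- pdm_sample(fit, 2)
  expect_lt(max(abs(sqrt(rowSums(pd$surface_points^2)) - r)), 1e-6)
  # ladder on a smooth blob, including the high degrees
  set.seed(1)
  blob <- otl_mesh(sp$vertices * (1 + 0.15 *
    as.numeric(sph_basis(sp$vertices, 3) %*% c(rep(0, 4), rnorm(12, 0, 0.3)))),
    sp$faces)
  ser <- spharm_degree_series(blob, c(1, 2, 3, 4, 5, 10, 15, 25))
  expect_true(all(diff(ser$rmse) <= 1e-12))
  expect_lt(ser$rmse[nrow(ser)], ser$rmse[1])
  expect_error(spharm_fit(icosphere(1), degree = 10), "underdetermined")
})

test_that("known-coefficient shapes round-trip through fit and sampling", {
  set.seed(2)
  ico <- icosphere(3)
  nb <- 25
  cf <- matrix(0, nb, 3)
  cf[2, 2] <- cf[3, 3] <- cf[4, 1] <- sqrt(4 * pi / 3)
  cf <- cf + matrix(rnorm(nb * 3, 0, 0.04), nb, 3)
  mesh <- otl_mesh(sph_basis(ico$vertices, 4) %*% cf, ico$faces)
  par <- list(directions = ico$vertices, flipped = 0, area_distortion = 1)
  fit <- spharm_fit(mesh, par, 4)
  expect_lt(max(abs(fit$coeffs - cf)) / max(abs(cf)), 1e-3)
  # fit -> pdm_sample -> refit reproduces coefficients at matched degree
  pd <- pdm_sample(fit, 3)
  mesh2 <- otl_mesh(pd$surface_points, pd$faces)
  par2 <- list(directions = pd$sample_points, flipped = 0, area_distortion = 1)
  fit2 <- spharm_fit(mesh2, par2, 4)
  expect_lt(max(abs(fit2$coeffs - cf)) / max(abs(cf)), 1e-6)
  # level-0 sampling is the bare icosahedron
  expect_equal(nrow(pdm_sample(fit, 0)$surface_points), 12)
})

test_that("correspondence alignment matches parameter-rotated copies", {
  set.seed(3)
  ico <- icosphere(3)
  nb <- 16
  cf <- matrix(0, nb, 3)
  cf[2, 2] <- 1.0; cf[3, 3] <- 1.6; cf[4, 1] <- 0.7   # distinct deg-1 axes
  cf <- cf + matrix(rnorm(nb * 3, 0, 0.03), nb, 3)
  par1 <- list(directions = ico$vertices, flipped = 0, area_distortion = 1)
  m1 <- spharm_fit(otl_mesh(sph_basis(ico$vertices, 3) %*% cf, ico$faces),
                   par1, 3)
  # same surface points, but the stored parametrization is rotated: the
  # shape-to-sphere map differs by a parameter rotation
  R <- random_rotation()
  par2 <- list(directions = ico$vertices %*% t(R), flipped = 0,
               area_distortion = 1)
  m2 <- spharm_fit(otl_mesh(sph_basis(ico$vertices, 3) %*% cf, ico$faces),
                   par2, 3)
  al <- correspondence_align(list(m1, m2))
  expect_lt(max(abs(al[[1]]$coeffs - al[[2]]$coeffs)), 1e-6)
  # idempotence: aligning the aligned models changes nothing
  al2 <- correspondence_align(al)
  expect_lt(max(abs(al2[[1]]$coeffs - al[[1]]$coeffs)), 1e-8)
  # degenerate spherical degree-1 part falls back with a warning per model
  msph <- spharm_fit(icosphere(3), NULL, 2)
  w <- capture_warnings(al_sph <- correspondence_align(list(msph, msph)))
  expect_true(all(grepl("degenerate", w)))
  expect_identical(al_sph[[1]]$coeffs, msph$coeffs)
})

test_that("mean shapes: identity, concentric spheres, translation equivariance", {
  sp <- icosphere(3)
  m1 <- spharm_fit(sp, NULL, 2)
  mm <- mean_shape(list(m1, m1), 2)
  pd <- pdm_sample(m1, 2)
  expect_lt(max(abs(mm$vertices - pd$surface_points)), 1e-10)
  big <- otl_mesh(sp$vertices * 3, sp$faces)
  m3 <- spharm_fit(big, NULL, 1)
  s1 <- spharm_fit(sp, NULL, 1)
  mid <- mean_shape(list(s1, m3), 3)
  expect_lt(max(abs(sqrt(rowSums(mid$vertices^2)) - 2)), 1e-6)
  expect_error(mean_shape(list(s1, spharm_fit(sp, NULL, 2)), 2), "degrees")
  # translation commutes with averaging
  sh <- c(0.4, -0.2, 0.9)
  tr <- lapply(list(sp, big), function(m) {
    m$vertices <- sweep(m$vertices, 2, sh, `+`); spharm_fit(m, NULL, 1)
  })
  mid_tr <- mean_shape(tr, 3)
  expect_lt(max(abs(mid_tr$vertices - sweep(mid$vertices, 2, sh, `+`))), 1e-4)
})

test_that("degree-series RMSE decreases from low to high degree on real organ shapes", {
  pop <- generate_population(population_spec(n_specimens = 2, seed = 15,
                                             mesh_subdivision = 3))
  utr <- pop[[1]]$meshes$utricle
  ser <- spharm_degree_series(utr, c(1, 3, 5, 10))
  expect_true(all(diff(ser$rmse) <= 1e-12))
  expect_lt(ser$rmse[4], 0.05 * ser$rmse[1] + 1e-6)
})
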