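test_that("similarity fit recovers exact transforms and scales triangles exactly", {
  set.seed(1)
  for (i in 1:5) {
    X <- matrix(rnorm(3 * (3 + i)), 3 + i, 3)
    R <- random_rotation(); s <- runif(1, 0.3, 3); t <- rnorm(3)
    Y <- s * X %*% t(R) + matrix(t, nrow(X), 3, byrow = TRUE)
    tr <- fit_similarity(X, Y)
    expect_lt(abs(tr$scale - s), 1e-10)
    expect_lt(max(abs(tr$rotation - R)), 1e-10)
    expect_lt(tr$rms_fiducial_error, 1e-10)
    expect_equal(det(tr$rotation), 1, tolerance = 1e-10)
    expect_lt(max(abs(apply_similarity(tr, X) - Y)), 1e-9)
  }
  # equilateral triangle to a scaled copy: scale equals the side ratio
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  tr2 <- fit_similarity(tri, 2.5 * tri)
  expect_equal(tr2$scale, 2.5, tolerance = 1e-12)
  expect_error(fit_similarity(cbind(1:4, 1:4, 1:4), cbind(1:4, 1:4, 1:4)),
               "collinear")
})

test_that("similarity RMS under isotropic noise tracks the noise floor", {
  set.seed(2)
  k <- 20; sigma <- 0.05
  rms <- replicate(40, {
    X <- matrix(rnorm(3 * k), k, 3)
    R <- random_rotation()
    Y <- X %*% t(R) + matrix(rnorm(3 * k, 0, sigma), k, 3)
    fit_similarity(X, Y)$rms_fiducial_error
  })
  # 7 fitted dof leave roughly (3k-7)/(3k) of the noise variance
  expect_equal(mean(rms), sigma * sqrt((3 * k - 7) / (3 * k)),
               tolerance = 0.05)
})

test_that("voxelization volume converges as the voxel shrinks", {
  sp <- icosphere(3)
  truth <- mesh_volume(sp)
  v1 <- voxel_volume(voxelize_mesh(sp, 0.2))
  v2 <- voxel_volume(voxelize_mesh(sp, 0.1))
  v3 <- voxel_volume(voxelize_mesh(sp, 0.05))
  expect_lt(abs(v3 - truth), abs(v1 - truth))
  expect_lt(abs(v3 - truth) / truth, 0.02)
  err <- c(abs(v1 - truth), abs(v2 - truth), abs(v3 - truth))
  expect_true(all(diff(err) < 0))
})

test_that("perilymph construction: subtraction volume, empty organs, containment", {
  sp <- icosphere(3)
  big <- otl_mesh(sp$vertices * 2, sp$faces)
  organ <- otl_mesh(sp$vertices * 0.9, sp$faces)
  peri <- build_perilymph_mesh(big, organ, NULL, voxel_size = 0.05)
  vol <- attr(peri, "volume")
  expect_equal(vol, mesh_volume(big) - mesh_volume(organ), tolerance = 0.04)
  expect_true(validate_genus0(peri, stop_on_fail = FALSE)$closed)
  # no organs: volume equals the vestibule volume
  peri0 <- build_perilymph_mesh(big, NULL, NULL, voxel_size = 0.05)
  expect_equal(attr(peri0, "volume"), mesh_volume(big), tolerance = 0.03)
  # organs poking outside trigger a containment error
  outside <- otl_mesh(sweep(sp$vertices, 2, c(2.5, 0, 0), `+`), sp$faces)
  expect_error(build_perilymph_mesh(big, outside, NULL, voxel_size = 0.1),
               "containment")
  # the shell surface hugs both walls: distances to the union of the input
  # surfaces concentrate near zero
  md_out <- mesh_distance(peri, big)$distances
  md_in <- mesh_distance(peri, organ)$distances
  near <- pmin(md_out, md_in)
  expect_gt(mean(near < 0.075), 0.95)
})

test_that("model assembly registers mean meshes into the consensus frame", {
  pop <- generate_population(population_spec(n_specimens = 4, seed = 16,
                                             mesh_subdivision = 2))
  ga <- gpa(pop_configs(pop))
  structures <- c("vestibule", "utricle", "saccule")
  mean_meshes <- lapply(structures, function(s) {
    vs <- Reduce(`+`, lapply(pop, function(p) p$meshes[[s]]$vertices)) /
      length(pop)
    m <- otl_mesh(vs, pop[[1]]$meshes[[s]]$faces)
    attr(m, "fiducials") <- otolithmorph:::.mean_mesh_fiducials(s, pop, 4)
    m
  })
  names(mean_meshes) <- structures
  model <- assemble_model(mean_meshes, ga, voxel_size = 0.05)
  expect_s3_class(model, "morphometric_model")
  expect_equal(nrow(model$consensus_landmarks), 22)
  expect_equal(rownames(model$perilymph_bony_landmarks), paste0("LM", 1:10))
  # registered fiducials land on the consensus landmarks (up to residual)
  for (s in structures)
    expect_lt(model$transforms[[s]]$rms_fiducial_error, 0.1)
  # wireframes carry the consensus semilandmark counts
  expect_equal(nrow(model$macular_wireframes$utricular), 16)
  expect_equal(nrow(model$macular_wireframes$saccular), 16)
  # meshes already in the consensus frame give identity transforms
  pre <- model$mean_utricle
  attr(pre, "fiducials") <- apply_similarity(
    model$transforms$utricle, attr(mean_meshes$utricle, "fiducials"))
  rownames(attr(pre, "fiducials")) <- rownames(attr(mean_meshes$utricle,
                                                    "fiducials"))
  mm2 <- mean_meshes; mm2$utricle <- pre
  model2 <- assemble_model(mm2, ga, build_perilymph = FALSE)
  expect_equal(model2$transforms$utricle$scale, 1, tolerance = 1e-6)
  expect_lt(max(abs(model2$mean_utricle$vertices - pre$vertices)), 1e-6)
  expect_error(assemble_model(mean_meshes[1:2], ga), "must contain")
  mm3 <- mean_meshes; attr(mm3$saccule, "fiducials") <- NULL
  expect_error(assemble_model(mm3, ga, build_perilymph = FALSE),
               "missing fiducials.*saccule")
})

test_that("assembled models move rigidly with the consensus (equivariance)", {
  pop <- generate_population(population_spec(n_specimens = 4, seed = 17,
                                             mesh_subdivision = 2))
  ga <- gpa(pop_configs(pop))
  structures <- c("vestibule", "utricle", "saccule")
  mean_meshes <- lapply(structures, function(s) {
    m <- pop[[1]]$meshes[[s]]
    attr(m, "fiducials") <- otolithmorph:::.mean_mesh_fiducials(s, pop, 4)
    m
  })
  names(mean_meshes) <- structures
  m1 <- assemble_model(mean_meshes, ga, build_perilymph = FALSE)
  R <- random_rotation()
  ga2 <- ga
  for (i in seq_len(dim(ga$coords)[1])) ga2$coords[i, , ] <- ga$coords[i, , ] %*% R
  ga2$consensus <- ga$consensus %*% R
  m2 <- assemble_model(mean_meshes, ga2, build_perilymph = FALSE)
  expect_lt(max(abs(m2$mean_utricle$vertices -
                      m1$mean_utricle$vertices %*% R)), 1e-6)
  expect_lt(max(abs(m2$consensus_landmarks - m1$consensus_landmarks %*% R)),
            1e-8)
})
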