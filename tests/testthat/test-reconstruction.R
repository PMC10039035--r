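# shared fixture: a small assembled model plus its generating population
make_model_fixture <- function(n = 5, seed = 18, subdiv = 2) {
  pop <- generate_population(population_spec(n_specimens = n, seed = seed,
                                             mesh_subdivision = subdiv))
  ga <- gpa(pop_configs(pop))
  structures <- c("vestibule", "utricle", "saccule")
  mean_meshes <- lapply(structures, function(s) {
    vs <- Reduce(`+`, lapply(pop, function(p) p$meshes[[s]]$vertices)) / n
    m <- otl_mesh(vs, pop[[1]]$meshes[[s]]$faces)
    attr(m, "fiducials") <- otolithmorph:::.mean_mesh_fiducials(s, pop, n)
    m
  })
  names(mean_meshes) <- structures
  model <- assemble_model(mean_meshes, ga, build_perilymph = FALSE)
  list(model = model, pop = pop)
}

test_that("mesh distances: self-zero, rigid invariance, consistent summaries", {
  sp <- icosphere(3)
  md0 <- mesh_distance(sp, sp)
  expect_lt(max(md0$distances), 1e-12)
  shell <- otl_mesh(sp$vertices * 1.2, sp$faces)
  md <- mesh_distance(shell, sp)
  expect_equal(max(abs(md$distances - 0.2)), 0, tolerance = 1e-8)
  R <- random_rotation(); t <- rnorm(3)
  move <- function(m) otl_mesh(m$vertices %*% R +
                                 matrix(t, nrow(m$vertices), 3, byrow = TRUE),
                               m$faces)
  md2 <- mesh_distance(move(shell), move(sp))
  expect_equal(md2$distances, md$distances, tolerance = 1e-10)
  # stored summary matches independent recomputation bit-for-bit
  expect_identical(md$summary[["mean"]], mean(md$distances))
  expect_identical(md$summary[["max"]], max(md$distances))
  expect_identical(md$summary[["iqr"]],
                   unname(quantile(md$distances, 0.75) -
                            quantile(md$distances, 0.25)))
})

test_that("reconstruction through the identity and similarity warps is exact", {
  fx <- make_model_fixture()
  model <- fx$model
  own <- model$perilymph_bony_landmarks
  rec <- reconstruct_organs(model, own)
  expect_lt(max(abs(rec$utricle$vertices - model$mean_utricle$vertices)),
            1e-10)
  expect_lt(max(abs(rec$saccule$vertices - model$mean_saccule$vertices)),
            1e-10)
  # a similarity image of the landmarks reproduces similarity-moved organs
  R <- random_rotation(); s <- 1.4; t <- c(0.3, -1, 2)
  tgt <- s * own %*% t(R) + matrix(t, nrow(own), 3, byrow = TRUE)
  rownames(tgt) <- rownames(own)
  rec2 <- reconstruct_organs(model, tgt)
  expect_lt(max(abs(rec2$utricle$vertices -
                      (s * model$mean_utricle$vertices %*% t(R) +
                         matrix(t, nrow(model$mean_utricle$vertices), 3,
                                byrow = TRUE)))), 1e-6)
  # reconstruction error at the bony landmarks is exactly zero
  expect_lt(max(abs(tps_apply(rec2$warp, own) - tgt)), 1e-8)
  expect_error(reconstruct_organs(model, own[1:6, ]), "lacks bony landmark")
})

test_that("reconstruction beats the unwarped model on deformed specimens", {
  fx <- make_model_fixture(seed = 19)
  model <- fx$model
  better <- vapply(fx$pop, function(sp) {
    rec <- reconstruct_organs(model, sp$config)
    e_warp <- mean(mesh_distance(rec$utricle, sp$meshes$utricle)$distances)
    e_null <- mean(mesh_distance(model$mean_utricle,
                                 sp$meshes$utricle)$distances)
    e_warp < e_null
  }, logical(1))
  expect_gte(mean(better), 0.8)
})

test_that("validation compares reconstruction error with inter-specimen variation", {
  fx <- make_model_fixture(seed = 20)
  val <- validate_reconstruction(fx$model, lapply(fx$pop, function(p)
    list(config = p$config, utricle = p$meshes$utricle,
         saccule = p$meshes$saccule)))
  expect_equal(nrow(val$results), 5)
  expect_true(all(is.finite(as.matrix(val$results[, 2:5]))))
  expect_true(all(val$reconstruction_distances >= 0))
  expect_lt(median(val$reconstruction_distances),
            median(val$interspecimen_distances))
  expect_lt(val$wilcoxon$p_value, 0.05)
  # identical specimens: all distances collapse and the test is inert
  clone <- lapply(1:2, function(i)
    list(config = landmark_config(fx$model$consensus_landmarks,
                                  rownames(fx$model$consensus_landmarks),
                                  specimen_id = sprintf("c%d", i)),
         utricle = fx$model$mean_utricle, saccule = fx$model$mean_saccule))
  # consensus singles lack LM1-10? they are present; perilymph landmarks
  val0 <- suppressWarnings(validate_reconstruction(fx$model, clone))
  expect_lt(max(val0$reconstruction_distances), 1e-8)
  expect_lt(max(val0$interspecimen_distances), 1e-8)
  expect_equal(val0$wilcoxon$p_value, 1)
})
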