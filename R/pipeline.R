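# Pipeline configuration and the top-level orchestration mirroring the
# analysis order: ingest/simulate -> equidistant resampling -> GPA +
# sliding -> shape/size regression batteries -> maculae orientation ->
# integration + modularity per landmark set -> SPHARM mean shapes ->
# model assembly -> reconstruction validation.

#' Pipeline configuration
#'
#' Defaults follow the package's standard analysis settings: 10,000
#' permutations for the integration/modularity tests, SPHARM degrees 25
#' (vestibule, saccule) and 15 (utricle), 0.05 mm voxel size for the
#' negative-space construction.
#'
#' @param seed Master seed; every stochastic stage derives its seed from
#'   it.
#' @param n_perm Permutations for 2B-PLS and CR tests.
#' @param slide Slide semilandmarks during superimposition.
#' @param spharm_degrees Named degrees per structure.
#' @param pdm_subdivision Icosphere subdivision of PDM sampling.
#' @param voxel_size Voxel size (mm) of the perilymph construction.
#' @param do_model Run the SPHARM + assembly + reconstruction stages.
#' @param n_model_specimens Specimens used for the SPHARM/mean-shape and
#'   reconstruction efficacy stages (default 5).
#' @param population A `population_spec` used when no data directory is
#'   given.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, n_perm = 10000L, slide = TRUE,
                            spharm_degrees = c(vestibule = 25L, saccule = 25L,
                                               utricle = 15L),
                            pdm_subdivision = 3L, voxel_size = 0.05,
                            do_model = TRUE, n_model_specimens = 5L,
                            population = NULL) {
  if (is.null(population))
    population <- population_spec(seed = seed, mesh_subdivision = 4L)
  structure(list(seed = as.integer(seed), n_perm = as.integer(n_perm),
                 slide = slide, spharm_degrees = spharm_degrees,
                 pdm_subdivision = as.integer(pdm_subdivision),
                 voxel_size = voxel_size, do_model = do_model,
                 n_model_specimens = as.integer(n_model_specimens),
                 population = population),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; a `population`
#' block mirrors [population_spec()]. Unknown keys are rejected so typos
#' do not silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  pop_args <- y$population
  y$population <- NULL
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(pop_args)) {
    known_p <- names(formals(population_spec))
    bad <- setdiff(names(pop_args), known_p)
    if (length(bad))
      stop("unknown population keys: ", paste(bad, collapse = ", "))
    y$population <- do.call(population_spec, pop_args)
  }
  if (!is.null(y$spharm_degrees)) y$spharm_degrees <- unlist(y$spharm_degrees)
  do.call(pipeline_config, y)
}

#' Resample a configuration's semilandmark curves to equidistant spacing
#'
#' Each curve is replaced by the same number of points placed at equal
#' arc length along its polyline; single landmarks are untouched.
#'
#' @param config A `landmark_config`.
#' @return The resampled `landmark_config`.
#' @export
resample_config_curves <- function(config) {
  P <- config$points
  for (cv in unique(config$curve[!is.na(config$curve)])) {
    idx <- which(!is.na(config$curve) & config$curve == cv)
    if (length(idx) >= 2L)
      P[idx, ] <- resample_equidistant(P[idx, , drop = FALSE], length(idx))
  }
  out <- config
  out$points <- P
  rownames(out$points) <- config$labels
  out
}

.derive_seed <- function(seed, offset) (seed * 1009L + offset) %% 2147483629L

#' Run the full analysis pipeline
#'
#' Executes all stages in order on either a directory of landmark/mesh
#' files or a generated synthetic population, and (optionally) writes a
#' deterministic report bundle of CSV/JSON artifacts.
#'
#' @param config A `pipeline_config`.
#' @param data_dir Optional directory of per-specimen `.fcsv`/`.csv`
#'   landmark files; `NULL` simulates from `config$population`.
#' @param out_dir Optional output directory for the report bundle.
#' @return A `pipeline_report` list with all stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), data_dir = NULL,
                         out_dir = NULL) {
  stage <- "ingest"
  res <- tryCatch({
    if (is.null(data_dir)) {
      pop <- generate_population(config$population)
      specimens <- lapply(pop, `[[`, "config")
      meshes <- lapply(pop, `[[`, "meshes")
    } else {
      files <- sort(list.files(data_dir, "\\.(fcsv|csv)$", full.names = TRUE))
      if (!length(files)) stop("no landmark files in ", data_dir)
      specimens <- lapply(files, read_landmarks)
      meshes <- NULL
      pop <- NULL
    }

    stage <- "superimposition"
    specimens_rs <- lapply(specimens, resample_config_curves)
    aligned <- gpa(specimens_rs)
    if (config$slide) aligned <- slide_semilandmarks(aligned)

    stage <- "regression_battery"
    battery <- regression_battery(aligned)

    stage <- "maculae_orientation"
    orientation <- maculae_orientation_analysis(specimens)

    stage <- "integration_modularity"
    intmod <- list()
    for (set_id in 1:6) {
      sd0 <- landmark_set(set_id)
      blocks <- subset_blocks(aligned, sd0)
      bn <- names(blocks)
      a <- flatten_shapes(blocks[[bn[1]]])
      b <- flatten_shapes(blocks[[bn[2]]])
      it <- two_block_pls(a, b, n_perm = config$n_perm,
                          seed = .derive_seed(config$seed, 100L + set_id))
      cr <- modularity_cr(a, b, n_perm = config$n_perm,
                          seed = .derive_seed(config$seed, 200L + set_id))
      intmod[[sprintf("set%d", set_id)]] <-
        data.frame(set_id = set_id, block_a = bn[1], block_b = bn[2],
                   r_pls = it$r_pls, pls_z = it$effect_size_z,
                   pls_p = it$p_value, cr = cr$cr, cr_z = cr$effect_size_z,
                   cr_p = cr$p_value, n_perm = config$n_perm,
                   stringsAsFactors = FALSE)
    }
    intmod <- do.call(rbind, intmod)

    model <- NULL; spharm <- NULL; validation <- NULL
    if (config$do_model && !is.null(meshes) && !is.null(meshes[[1]])) {
      stage <- "spharm"
      nm <- min(config$n_model_specimens, length(meshes))
      structures <- c("vestibule", "utricle", "saccule")
      models <- list()
      for (s in structures) {
        L <- config$spharm_degrees[[s]]
        ml <- lapply(seq_len(nm), function(i) {
          mesh <- meshes[[i]][[s]]
          Leff <- min(L, floor(sqrt(nrow(mesh$vertices))) - 1L)
          spharm_fit(mesh, degree = Leff)
        })
        models[[s]] <- correspondence_align(ml)
      }
      spharm <- list(
        models = models,
        rmse = vapply(structures, function(s)
          mean(vapply(models[[s]], function(m) m$rmse, numeric(1))),
          numeric(1)))

      stage <- "assembly"
      mean_meshes <- lapply(structures, function(s)
        mean_shape(models[[s]], config$pdm_subdivision))
      names(mean_meshes) <- structures
      for (s in structures)
        attr(mean_meshes[[s]], "fiducials") <- .mean_mesh_fiducials(s, pop, nm)
      model <- assemble_model(mean_meshes, aligned,
                              voxel_size = config$voxel_size)

      stage <- "reconstruction"
      val_spec <- lapply(seq_len(nm), function(i)
        list(config = specimens[[i]], utricle = meshes[[i]]$utricle,
             saccule = meshes[[i]]$saccule))
      validation <- validate_reconstruction(model, val_spec)
    }

    list(aligned = aligned, battery = battery, orientation = orientation,
         integration_modularity = intmod, spharm = spharm, model = model,
         validation = validation, config = config,
         specimens = specimens, population = pop)
  }, error = function(e)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE))

  if (!is.null(out_dir)) .write_report(res, out_dir)
  class(res) <- "pipeline_report"
  res
}

# fiducials for a synthetic mean mesh: average of per-specimen parametric
# landmark positions on that structure (labels match the consensus)
.mean_mesh_fiducials <- function(structure, pop, nm) {
  base <- synthetic_fiducials(structure)
  labs <- rownames(base)
  acc <- 0
  for (i in seq_len(nm)) {
    cfg <- pop[[i]]$config
    acc <- acc + cfg$points[match(labs, cfg$labels), , drop = FALSE]
  }
  out <- acc / nm
  rownames(out) <- labs
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report:\n")
  cat(sprintf("  %d specimens, GPA %s\n", dim(x$aligned$coords)[1],
              if (x$aligned$converged) "converged" else "not converged"))
  cat(sprintf("  battery: %d models (%d failed)\n", nrow(x$battery),
              sum(!is.na(x$battery$error))))
  cat(sprintf("  integration/modularity: %d landmark sets\n",
              nrow(x$integration_modularity)))
  if (!is.null(x$validation))
    cat(sprintf("  reconstruction: %d specimens, rank-sum p = %.3g\n",
                nrow(x$validation$results), x$validation$wilcoxon$p_value))
  invisible(x)
}

.write_report <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(d, f) write.csv(d, file.path(out_dir, f), row.names = FALSE)
  wcsv(res$battery, "regression_battery.csv")
  wcsv(res$integration_modularity, "integration_modularity.csv")
  wcsv(res$orientation$angles, "maculae_angles.csv")
  wcsv(res$orientation$summary, "maculae_angle_summary.csv")
  wcsv(res$orientation$interplane_regression$table, "interplane_angles.csv")
  if (!is.null(res$validation)) {
    wcsv(res$validation$results, "reconstruction_summary.csv")
    jsonlite::write_json(
      list(wilcoxon_statistic = res$validation$wilcoxon$statistic,
           wilcoxon_p = res$validation$wilcoxon$p_value),
      file.path(out_dir, "reconstruction_test.json"),
      auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$model)) save_model_bundle(res$model,
                                             file.path(out_dir, "model"))
  cfg <- res$config
  cfg$population <- unclass(cfg$population)
  jsonlite::write_json(
    list(seed = cfg$seed, n_perm = cfg$n_perm, slide = cfg$slide,
         spharm_degrees = as.list(cfg$spharm_degrees),
         pdm_subdivision = cfg$pdm_subdivision,
         voxel_size = cfg$voxel_size,
         population = cfg$population,
         landmark_index_note = "labels LM1-LM22/SemiLM1-5 are 1-based; array indices are 1-based R indices"),
    file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA)
  # consensus landmarks for downstream use
  cons <- res$aligned$consensus
  write_fcsv(landmark_config(cons, res$aligned$labels,
                             specimen_id = "consensus"),
             file.path(out_dir, "consensus.fcsv"))
  invisible(out_dir)
}
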