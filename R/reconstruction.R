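# Reconstruction of membranous organs from bony landmarks and validation
# against true meshes.

#' Reconstruct membranous organs from bony landmarks
#'
#' Fits a thin-plate-spline warp from the model's bony landmarks (LM1-10
#' on the assembled model) to a target specimen's bony landmarks and maps
#' the model's organ surfaces through it. The TPS interpolates the
#' landmarks exactly, so reconstruction error at the bony landmark
#' positions is zero by construction.
#'
#' @param model A `morphometric_model` from [assemble_model()].
#' @param target_bony_landmarks 10 x 3 matrix with rownames LM1..LM10 (or
#'   a `landmark_config` containing those labels).
#' @return List with `utricle` and `saccule` reconstructed `otl_mesh`
#'   objects and the fitted `warp`.
#' @export
reconstruct_organs <- function(model, target_bony_landmarks) {
  src <- model$perilymph_bony_landmarks
  if (inherits(target_bony_landmarks, "landmark_config")) {
    cfg <- target_bony_landmarks
    idx <- match(rownames(src), cfg$labels)
    if (anyNA(idx))
      stop("target lacks bony landmark(s): ",
           paste(rownames(src)[is.na(idx)], collapse = ", "))
    tgt <- cfg$points[idx, , drop = FALSE]
  } else {
    tgt <- as.matrix(target_bony_landmarks)
    if (!is.null(rownames(tgt))) {
      idx <- match(rownames(src), rownames(tgt))
      if (anyNA(idx))
        stop("target lacks bony landmark(s): ",
             paste(rownames(src)[is.na(idx)], collapse = ", "))
      tgt <- tgt[idx, , drop = FALSE]
    }
  }
  if (nrow(tgt) != nrow(src)) stop("landmark count mismatch")
  # near-coplanar bony sets are handled by the kernel regularization
  sv3 <- svd(sweep(src, 2, colMeans(src)))$d
  if (sv3[3] < 1e-6 * sv3[1])
    warning("near-coplanar bony landmarks: warp is regularized")
  warp <- tps_fit(src, tgt)
  list(utricle = warp_mesh(warp, model$mean_utricle),
       saccule = warp_mesh(warp, model$mean_saccule),
       warp = warp)
}

#' Closest-point distances from one mesh to another
#'
#' For every vertex of `test`, the Euclidean distance to the closest
#' point on the `reference` surface (point-to-triangle, not
#' point-to-vertex). Degenerate reference triangles are skipped; their
#' count is reported.
#'
#' @param test,reference `otl_mesh` objects (or a point matrix for
#'   `test`).
#' @return A `mesh_distance` list: `distances` (per test vertex),
#'   `summary` (`mean`, `sd`, `max`, `iqr`), `skipped_triangles`.
#' @export
mesh_distance <- function(test, reference) {
  pts <- if (inherits(test, "otl_mesh")) test$vertices else as.matrix(test)
  if (!nrow(pts) || !nrow(reference$faces)) stop("empty mesh")
  d <- .cpp_point_mesh_distance(pts, reference$vertices, reference$faces)
  skipped <- attr(d, "skipped_triangles")
  d <- as.numeric(d)
  structure(list(distances = d,
                 summary = c(mean = mean(d), sd = sd(d), max = max(d),
                             iqr = unname(quantile(d, 0.75) - quantile(d, 0.25))),
                 skipped_triangles = skipped),
            class = "mesh_distance")
}

#' @export
print.mesh_distance <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "mesh_distance: mean %.4g (sd %.4g), max %.4g, IQR %.4g mm (%d vertices)\n",
    s["mean"], s["sd"], s["max"], s["iqr"], length(x$distances)))
  invisible(x)
}

#' Validate organ reconstruction against true meshes
#'
#' Reconstructs each specimen's membranous organs from its bony landmarks,
#' measures vertex distances to the specimen's true organ meshes, and
#' compares the pooled reconstruction-error distances against pooled
#' inter-specimen distances (true organ meshes of different individuals,
#' mutually aligned by similarity registration on the full single-landmark
#' set) with a Wilcoxon rank-sum test.
#'
#' @param model A `morphometric_model`.
#' @param specimens List of specimen entries, each a list with
#'   `config` (`landmark_config` with LM1-10 and the full single set),
#'   `utricle` and `saccule` true `otl_mesh` surfaces.
#' @param reference_index Specimen used as the alignment reference for
#'   the inter-specimen baseline (default 1).
#' @return List with `results` (per-specimen distance summaries),
#'   `reconstruction_distances`, `interspecimen_distances`, `wilcoxon`
#'   (rank-sum statistic and p-value) and per-specimen reconstructions.
#' @export
validate_reconstruction <- function(model, specimens, reference_index = 1L) {
  if (length(specimens) < 2L) stop("need at least 2 specimens")
  singles <- paste0("LM", 1:22)

  recon_d <- list()
  results <- list()
  recons <- list()
  for (i in seq_along(specimens)) {
    sp <- specimens[[i]]
    rec <- reconstruct_organs(model, sp$config)
    du <- mesh_distance(rec$utricle, sp$utricle)
    ds <- mesh_distance(rec$saccule, sp$saccule)
    d <- c(du$distances, ds$distances)
    recon_d[[i]] <- d
    recons[[i]] <- rec
    results[[i]] <- data.frame(
      specimen_id = sp$config$specimen_id,
      mean_mm = mean(d), sd_mm = sd(d), max_mm = max(d),
      iqr_mm = unname(quantile(d, 0.75) - quantile(d, 0.25)),
      n_vertices = length(d), stringsAsFactors = FALSE)
  }

  # inter-specimen baseline: align everyone onto the reference specimen by
  # similarity registration on the shared single landmarks, then measure
  # pairwise true-mesh distances
  ref <- specimens[[reference_index]]
  get_singles <- function(cfg) {
    labs <- intersect(singles, cfg$labels)
    cfg$points[match(labs, cfg$labels), , drop = FALSE]
  }
  ref_pts <- get_singles(ref$config)
  aligned_meshes <- lapply(specimens, function(sp) {
    pts <- get_singles(sp$config)
    labs <- intersect(rownames(ref_pts), rownames(pts))
    tr <- fit_similarity(pts[labs, , drop = FALSE],
                         ref_pts[labs, , drop = FALSE])
    list(utricle = apply_similarity(tr, sp$utricle),
         saccule = apply_similarity(tr, sp$saccule))
  })
  inter_d <- c()
  n <- length(specimens)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    inter_d <- c(inter_d,
                 mesh_distance(aligned_meshes[[i]]$utricle,
                               aligned_meshes[[j]]$utricle)$distances,
                 mesh_distance(aligned_meshes[[i]]$saccule,
                               aligned_meshes[[j]]$saccule)$distances)
  }
  recon_all <- unlist(recon_d)
  # numerical floor: sub-nanometer distances on mm-scale meshes are zero
  recon_all[recon_all < 1e-9] <- 0
  inter_d[inter_d < 1e-9] <- 0
  wt <- wilcoxon_rank_sum(recon_all, inter_d)
  list(results = do.call(rbind, results),
       reconstruction_distances = recon_all,
       interspecimen_distances = inter_d,
       wilcoxon = wt,
       reconstructions = recons)
}
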