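# Morphometric-model assembly: fiducial similarity registration of mean
# meshes onto the consensus landmark frame and construction of the
# perilymphatic "negative space" mesh by voxel boolean subtraction.

#' Closed-form least-squares similarity transform (fiducial registration)
#'
#' Umeyama's solution for the rotation (determinant +1, reflections
#' excluded), isotropic scale and translation minimizing the summed
#' squared distance between corresponding fiducials.
#'
#' @param source_fiducials,target_fiducials k x 3 matrices of
#'   corresponding points (k >= 3, non-collinear).
#' @return A `similarity_transform`: `scale`, `rotation` (3 x 3),
#'   `translation`, `rms_fiducial_error`.
#' @export
fit_similarity <- function(source_fiducials, target_fiducials) {
  X <- as.matrix(source_fiducials); Y <- as.matrix(target_fiducials)
  if (!all(dim(X) == dim(Y)) || nrow(X) < 3L)
    stop("need >= 3 corresponding fiducial pairs")
  if (qr(sweep(X, 2, colMeans(X)))$rank < 2L)
    stop("collinear fiducials")
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  S <- crossprod(Xc, Yc) / nrow(X)
  sv <- svd(S)
  d <- sign(det(sv$v %*% t(sv$u))); if (d == 0) d <- 1
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  varX <- sum(Xc^2) / nrow(X)
  s <- sum(sv$d * c(1, 1, d)) / varX
  t <- my - s * as.numeric(R %*% mx)
  resid <- Y - (s * X %*% t(R) + matrix(t, nrow(X), 3, byrow = TRUE))
  structure(list(scale = s, rotation = R, translation = t,
                 rms_fiducial_error = sqrt(mean(rowSums(resid^2)))),
            class = "similarity_transform")
}

#' Apply a similarity transform to points or a mesh
#'
#' @param transform A `similarity_transform`.
#' @param x n x 3 matrix or `otl_mesh`.
#' @return Transformed points / mesh.
#' @export
apply_similarity <- function(transform, x) {
  tf <- function(P) transform$scale * P %*% t(transform$rotation) +
    matrix(transform$translation, nrow(P), 3, byrow = TRUE)
  if (inherits(x, "otl_mesh")) {
    x$vertices <- tf(x$vertices); x
  } else tf(as.matrix(x))
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("similarity_transform: scale %.4f, rms fiducial error %.4g mm\n",
              x$scale, x$rms_fiducial_error))
  invisible(x)
}

#' Voxelize a closed mesh on a regular grid
#'
#' Fills every voxel whose center lies inside the surface
#' (vertical-ray parity counting).
#'
#' @param mesh A closed `otl_mesh`.
#' @param voxel_size Voxel edge length (mm).
#' @param bounds Optional 2 x 3 matrix (min/max corner); defaults to the
#'   mesh bounding box padded by one voxel.
#' @return A `voxel_grid` list: `array` (logical nx x ny x nz), `origin`,
#'   `voxel_size`.
#' @export
voxelize_mesh <- function(mesh, voxel_size = 0.05, bounds = NULL) {
  if (is.null(bounds)) {
    lo <- apply(mesh$vertices, 2, min) - 2 * voxel_size
    hi <- apply(mesh$vertices, 2, max) + 2 * voxel_size
  } else {
    lo <- bounds[1, ]; hi <- bounds[2, ]
  }
  dims <- as.integer(ceiling((hi - lo) / voxel_size))
  arr <- .cpp_voxelize(mesh$vertices, mesh$faces, as.numeric(lo),
                       voxel_size, dims)
  structure(list(array = arr, origin = as.numeric(lo),
                 voxel_size = voxel_size),
            class = "voxel_grid")
}

#' Volume of a voxel grid
#' @param grid A `voxel_grid`.
#' @return Volume in mm^3.
#' @export
voxel_volume <- function(grid) sum(grid$array) * grid$voxel_size^3

#' Build the perilymphatic negative-space mesh
#'
#' Voxelizes the bony vestibule and the membranous organs on one grid,
#' boolean-subtracts the organ voxels from the vestibule voxels, and
#' extracts the boundary surface of the remaining set — the space filled
#' by perilymph in life.
#'
#' @param vestibule,utricle,saccule Closed `otl_mesh` surfaces (organs
#'   contained in the vestibule; `NULL` organs are allowed and subtract
#'   nothing).
#' @param voxel_size Voxel edge length in mm (default 0.05, matching
#'   typical membranous labelmap spacing).
#' @param containment_tol Fraction of organ voxels allowed outside the
#'   vestibule before a containment error is raised (default 0.005).
#' @return An `otl_mesh` of the negative space with attributes
#'   `volume` (voxel volume, mm^3) and `grid` (the boolean `voxel_grid`).
#' @export
build_perilymph_mesh <- function(vestibule, utricle = NULL, saccule = NULL,
                                 voxel_size = 0.05, containment_tol = 0.005) {
  lo <- apply(vestibule$vertices, 2, min) - 2 * voxel_size
  hi <- apply(vestibule$vertices, 2, max) + 2 * voxel_size
  bounds <- rbind(lo, hi)
  gv <- voxelize_mesh(vestibule, voxel_size, bounds)
  keep <- gv$array
  for (organ in list(utricle, saccule)) {
    if (is.null(organ)) next
    go <- voxelize_mesh(organ, voxel_size, bounds)
    outside <- sum(go$array & !gv$array)
    if (outside > containment_tol * max(1, sum(go$array)))
      stop(sprintf("containment error: %d organ voxels outside the vestibule",
                   outside))
    keep <- keep & !go$array
  }
  surf <- .cpp_voxel_surface(keep, gv$origin, voxel_size, dim(gv$array))
  mesh <- otl_mesh(surf$vertices, surf$faces)
  attr(mesh, "volume") <- sum(keep) * voxel_size^3
  attr(mesh, "grid") <- structure(list(array = keep, origin = gv$origin,
                                       voxel_size = voxel_size),
                                  class = "voxel_grid")
  mesh
}

#' Assemble the morphometric model
#'
#' Registers each mean mesh onto the consensus landmark frame by
#' similarity fiducial registration (each mesh carries its own fiducial
#' landmarks, named to match consensus labels), builds the consensus
#' macular wireframes from the SemiLM4/SemiLM5 semilandmark consensus,
#' and constructs the perilymphatic negative-space mesh.
#'
#' @param mean_meshes Named list with `vestibule`, `utricle`, `saccule`
#'   `otl_mesh` objects; each must have a `fiducials` attribute (k x 3
#'   matrix with rownames giving landmark labels).
#' @param consensus An `aligned_shapes` object whose consensus supplies
#'   the landmark frame (full scheme or singles).
#' @param voxel_size Voxel size for the negative-space construction
#'   (default 0.05 mm).
#' @param build_perilymph Construct the voxel negative-space mesh
#'   (default `TRUE`).
#' @param scale_to_mean_size Express the model frame in mm by scaling the
#'   (unit-centroid-size) consensus up by the mean specimen centroid size
#'   (default `TRUE`), so voxel sizes and distances keep physical units.
#' @return A `morphometric_model`: registered `mean_vestibule`,
#'   `mean_utricle`, `mean_saccule`, `consensus_landmarks` (singles-only
#'   k x 3 with labels), `macular_wireframes`, `perilymph_mesh` (or
#'   `NULL`), `perilymph_bony_landmarks` (LM1-10 coordinates in the model
#'   frame) and the fitted `transforms`.
#' @export
assemble_model <- function(mean_meshes, consensus, voxel_size = 0.05,
                           build_perilymph = TRUE, scale_to_mean_size = TRUE) {
  stopifnot(inherits(consensus, "aligned_shapes"))
  need <- c("vestibule", "utricle", "saccule")
  if (!all(need %in% names(mean_meshes)))
    stop("mean_meshes must contain: ", paste(need, collapse = ", "))
  cons <- consensus$consensus
  if (scale_to_mean_size && isTRUE(consensus$scale))
    cons <- cons * mean(consensus$centroid_sizes)
  rownames(cons) <- consensus$labels
  registered <- list()
  transforms <- list()
  for (nm in need) {
    mesh <- mean_meshes[[nm]]
    fid <- attr(mesh, "fiducials")
    if (is.null(fid) || is.null(rownames(fid)))
      stop("missing fiducials on mean mesh: ", nm)
    labs <- intersect(rownames(fid), rownames(cons))
    if (length(labs) < 3L)
      stop("mean mesh ", nm, " shares fewer than 3 fiducial labels with the consensus")
    tr <- fit_similarity(fid[labs, , drop = FALSE], cons[labs, , drop = FALSE])
    out <- apply_similarity(tr, mesh)
    attr(out, "fiducials") <- apply_similarity(tr, fid)
    rownames(attr(out, "fiducials")) <- rownames(fid)
    registered[[nm]] <- out
    transforms[[nm]] <- tr
  }
  singles <- consensus$role == "single"
  cons_singles <- cons[singles, , drop = FALSE]
  wire <- lapply(c(utricular = "SemiLM4", saccular = "SemiLM5"), function(cv) {
    idx <- which(!is.na(consensus$curve) & consensus$curve == cv)
    if (!length(idx)) return(NULL)
    cons[idx, , drop = FALSE]
  })
  bony_labels <- paste0("LM", 1:10)
  bl <- bony_labels[bony_labels %in% rownames(cons)]
  peri <- NULL
  if (build_perilymph)
    peri <- build_perilymph_mesh(registered$vestibule, registered$utricle,
                                 registered$saccule, voxel_size)
  structure(list(mean_vestibule = registered$vestibule,
                 mean_utricle = registered$utricle,
                 mean_saccule = registered$saccule,
                 consensus_landmarks = cons_singles,
                 macular_wireframes = wire,
                 perilymph_mesh = peri,
                 perilymph_bony_landmarks = cons[bl, , drop = FALSE],
                 transforms = transforms,
                 voxel_size = voxel_size),
            class = "morphometric_model")
}

#' @export
print.morphometric_model <- function(x, ...) {
  cat("morphometric_model:\n")
  for (nm in c("mean_vestibule", "mean_utricle", "mean_saccule"))
    cat(sprintf("  %s: %d vertices\n", nm, nrow(x[[nm]]$vertices)))
  cat(sprintf("  %d consensus single landmarks, %d bony landmarks on model\n",
              nrow(x$consensus_landmarks), nrow(x$perilymph_bony_landmarks)))
  invisible(x)
}

#' Save / load a morphometric model bundle
#'
#' The bundle is a directory of plain-text artifacts: meshes as OBJ,
#' landmarks as `.fcsv`, and a JSON manifest with the transforms and
#' voxel size.
#'
#' @param model A `morphometric_model`.
#' @param dir Bundle directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
save_model_bundle <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("mean_vestibule", "mean_utricle", "mean_saccule"))
    write_mesh(model[[nm]], file.path(dir, paste0(nm, ".obj")))
  if (!is.null(model$perilymph_mesh))
    write_mesh(model$perilymph_mesh, file.path(dir, "perilymph.obj"))
  write_fcsv(landmark_config(model$consensus_landmarks,
                             rownames(model$consensus_landmarks),
                             specimen_id = "consensus"),
             file.path(dir, "consensus_landmarks.fcsv"))
  write_fcsv(landmark_config(model$perilymph_bony_landmarks,
                             rownames(model$perilymph_bony_landmarks),
                             specimen_id = "perilymph"),
             file.path(dir, "perilymph_bony_landmarks.fcsv"))
  manifest <- list(
    voxel_size = model$voxel_size,
    transforms = lapply(model$transforms, function(tr)
      list(scale = tr$scale, rotation = as.numeric(tr$rotation),
           translation = tr$translation,
           rms_fiducial_error = tr$rms_fiducial_error)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
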