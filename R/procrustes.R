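# Ordinary and generalized Procrustes superimposition.

.center <- function(x) sweep(x, 2, colMeans(x))

.optimal_rotation <- function(moving, fixed) {
  # least-squares rotation (det = +1, reflections excluded) taking centered
  # `moving` onto centered `fixed`
  A <- crossprod(moving, fixed)        # 3x3 cross-covariance
  sv <- svd(A)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  S <- diag(c(1, 1, d))
  R <- sv$u %*% S %*% t(sv$v)          # maximizes tr(R' A), det(R) = +1
  list(R = R, sv = sum(sv$d * c(1, 1, d)))
}

#' Ordinary Procrustes alignment of one configuration onto another
#'
#' Least-squares superimposition of `moving` onto `fixed` by translation,
#' rotation (determinant +1; reflections are never introduced implicitly)
#' and, optionally, scale. The reported distance is the full Procrustes
#' distance: the root summed squared residual after both configurations are
#' scaled to unit centroid size.
#'
#' @param moving,fixed `landmark_config` objects or k x 3 matrices with
#'   identical point ordering.
#' @param allow_scale Include a scale factor in the fitted transform
#'   (default `TRUE`).
#' @return List with `aligned` (transformed moving configuration, original
#'   scale convention of `fixed`), `rotation`, `scale`, `translation`, and
#'   `distance` (unit-size full Procrustes distance).
#' @export
opa_align <- function(moving, fixed, allow_scale = TRUE) {
  X <- .config_points(fixed)
  Y <- .config_points(moving)
  if (!all(dim(X) == dim(Y)))
    stop("configurations must have the same number of points")
  if (nrow(X) < 3L) stop("need at least 3 points")
  Xc <- .center(X); Yc <- .center(Y)
  if (qr(Xc)$rank < 2L || qr(Yc)$rank < 2L)
    stop("degenerate configuration: rank < 2")

  rot <- .optimal_rotation(Yc, Xc)
  s <- if (allow_scale) rot$sv / sum(Yc^2) else 1
  aligned <- s * Yc %*% rot$R
  translation <- colMeans(X) - s * colMeans(Y) %*% rot$R
  aligned <- sweep(aligned, 2, colMeans(X), `+`)

  # Procrustes distance: residual after both configurations are scaled to
  # unit centroid size and optimally rotated (symmetric in its arguments);
  # computed as a direct residual norm to avoid cancellation near zero
  Xu <- Xc / sqrt(sum(Xc^2)); Yu <- Yc / sqrt(sum(Yc^2))
  rot_u <- .optimal_rotation(Yu, Xu)
  d2 <- sum((Xu - Yu %*% rot_u$R)^2)
  list(aligned = aligned, rotation = rot$R, scale = s,
       translation = as.numeric(translation), distance = sqrt(d2))
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition of two or more configurations onto their
#' evolving consensus. Each configuration is centered and (by default)
#' scaled to unit centroid size; centroid sizes are recorded before
#' scaling for downstream size analyses. Iteration stops when the change
#' in the total Procrustes sum of squares falls below `tol`.
#'
#' @param configs List of `landmark_config` objects (or k x 3 matrices)
#'   with identical point ordering.
#' @param scale Scale every configuration to unit centroid size (classical
#'   full-Procrustes superimposition, default `TRUE`).
#' @param tol Convergence tolerance on the change in the summed squared
#'   distance to the consensus (default 1e-10).
#' @param max_iter Maximum number of iterations (default 100).
#' @param tangent_project Project aligned coordinates into the tangent
#'   space at the consensus (orthogonal projection). Off by default: raw
#'   Procrustes residuals are used downstream.
#' @return An `aligned_shapes` object: `coords` (n x k x 3 array),
#'   `consensus` (k x 3), `centroid_sizes`, `iterations`, `converged`,
#'   `ss_trace` (summed squared distance per iteration), plus the point
#'   metadata (`labels`, `role`, `curve`, `block`) of the first
#'   configuration.
#' @export
gpa <- function(configs, scale = TRUE, tol = 1e-10, max_iter = 100L,
                tangent_project = FALSE) {
  if (length(configs) < 2L) stop("need at least 2 configurations")
  mats <- lapply(configs, .config_points)
  k <- nrow(mats[[1]])
  if (!all(vapply(mats, nrow, 1L) == k))
    stop("configurations differ in point count")
  n <- length(mats)
  meta <- if (inherits(configs[[1]], "landmark_config")) configs[[1]] else NULL
  ids <- vapply(seq_len(n), function(i) {
    if (inherits(configs[[i]], "landmark_config")) configs[[i]]$specimen_id
    else sprintf("spec%02d", i)
  }, character(1))

  sizes <- vapply(mats, centroid_size, numeric(1))
  X <- lapply(seq_len(n), function(i) {
    xc <- .center(mats[[i]])
    if (scale) xc / sizes[i] else xc
  })

  consensus <- X[[1]]
  ss_old <- Inf
  ss_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      rot <- .optimal_rotation(X[[i]], consensus)
      X[[i]] <- X[[i]] %*% rot$R
      if (scale) {
        # full Procrustes scaling towards the consensus, then renormalize
        X[[i]] <- X[[i]] / sqrt(sum(X[[i]]^2))
      }
    }
    consensus <- Reduce(`+`, X) / n
    if (scale) consensus <- consensus / sqrt(sum(consensus^2))
    ss <- sum(vapply(X, function(x) sum((x - consensus)^2), numeric(1)))
    ss_trace <- c(ss_trace, ss)
    if (is.finite(ss_old) && abs(ss_old - ss) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    ss_old <- ss
  }

  consensus <- Reduce(`+`, X) / n     # reported consensus: the pointwise mean
  coords <- array(NA_real_, dim = c(n, k, 3),
                  dimnames = list(ids, rownames(mats[[1]]), c("x", "y", "z")))
  for (i in seq_len(n)) coords[i, , ] <- X[[i]]
  if (tangent_project) {
    # orthogonal projection onto the tangent space at the consensus
    v <- as.numeric(consensus)
    v <- v / sqrt(sum(v^2))
    for (i in seq_len(n)) {
      xi <- as.numeric(coords[i, , ])
      coords[i, , ] <- xi - (sum(xi * v) - 1) * v
    }
  }
  structure(list(coords = coords, consensus = consensus,
                 centroid_sizes = sizes, iterations = iter,
                 converged = converged, ss_trace = ss_trace,
                 scale = scale,
                 specimen_ids = ids,
                 labels = if (!is.null(meta)) meta$labels else rownames(mats[[1]]),
                 role = if (!is.null(meta)) meta$role else rep("single", k),
                 curve = if (!is.null(meta)) meta$curve else rep(NA_character_, k),
                 block = if (!is.null(meta)) meta$block else rep(NA_character_, k)),
            class = "aligned_shapes")
}

#' @export
print.aligned_shapes <- function(x, ...) {
  cat(sprintf("aligned_shapes: %d specimens x %d landmarks (GPA %s in %d iterations)\n",
              dim(x$coords)[1], dim(x$coords)[2],
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Full Procrustes distance between two configurations
#'
#' @inheritParams opa_align
#' @return Non-negative scalar distance.
#' @export
procrustes_distance <- function(moving, fixed) {
  opa_align(moving, fixed, allow_scale = TRUE)$distance
}

#' Split a jointly superimposed shape set into tissue blocks
#'
#' Returns coordinate subsets of an already superimposed set without any
#' re-superimposition (the "within a configuration" approach): relative
#' position and scale of the blocks are preserved exactly as placed by the
#' joint alignment.
#'
#' @param aligned An `aligned_shapes` object from [gpa()].
#' @param setdef A `landmark_set` (or a named block vector). Points absent
#'   from the set are dropped; the remaining points are split by block.
#' @return Named list of `aligned_shapes` views, one per block, each with
#'   the subset's coordinates and the original consensus rows.
#' @export
subset_blocks <- function(aligned, setdef = landmark_set(1)) {
  blocks <- if (inherits(setdef, "landmark_set")) setdef$blocks else setdef
  missing <- setdiff(names(blocks), aligned$labels)
  if (length(missing))
    stop("unknown labels in set definition: ", paste(missing, collapse = ", "))
  out <- lapply(unique(blocks), function(b) {
    labs <- names(blocks)[blocks == b]
    idx <- match(labs, aligned$labels)
    v <- aligned
    v$coords <- aligned$coords[, idx, , drop = FALSE]
    v$consensus <- aligned$consensus[idx, , drop = FALSE]
    v$labels <- aligned$labels[idx]
    v$role <- aligned$role[idx]
    v$curve <- aligned$curve[idx]
    v$block <- aligned$block[idx]
    v$subset_of <- b
    v
  })
  names(out) <- unique(blocks)
  out
}

#' Flatten an aligned shape set to an n x 3k data matrix
#'
#' @param aligned An `aligned_shapes` object (or view).
#' @return n x 3k numeric matrix (landmark-major column order
#'   x1,y1,z1,x2,...).
#' @export
flatten_shapes <- function(aligned) {
  d <- dim(aligned$coords)
  n <- d[1]; k <- d[2]
  out <- matrix(NA_real_, n, 3 * k)
  for (i in seq_len(n)) out[i, ] <- as.numeric(t(aligned$coords[i, , ]))
  colnames(out) <- paste0(rep(aligned$labels, each = 3), "_", c("x", "y", "z"))
  rownames(out) <- aligned$specimen_ids
  out
}

#' Intraobserver repeatability check
#'
#' Compares Procrustes distances among repeated landmarkings of a single
#' specimen with the distances between distinct individuals: measurement
#' error is negligible when the largest within-replicate distance falls
#' well below the smallest between-individual distance. Also reports
#' per-landmark variance of the aligned replicate coordinates
#' (semilandmarks excluded).
#'
#' @param replicates List of `landmark_config` objects: repeated
#'   landmarkings of one specimen.
#' @param individuals List of `landmark_config` objects: the study
#'   individuals.
#' @return List with `max_replicate_distance`, `min_individual_distance`,
#'   `landmark_variance` (per-single-landmark summed coordinate variance
#'   of aligned replicates) and `most_variable_landmark`.
#' @export
repeatability_analysis <- function(replicates, individuals) {
  stopifnot(length(replicates) >= 2L, length(individuals) >= 2L)
  dmax <- 0
  for (i in seq_along(replicates)[-1]) for (j in seq_len(i - 1L))
    dmax <- max(dmax, procrustes_distance(replicates[[i]], replicates[[j]]))
  dmin <- Inf
  for (i in seq_along(individuals)[-1]) for (j in seq_len(i - 1L))
    dmin <- min(dmin, procrustes_distance(individuals[[i]], individuals[[j]]))
  ga <- gpa(replicates)
  single <- ga$role == "single"
  lv <- apply(ga$coords[, single, , drop = FALSE], 2, function(m) sum(apply(m, 2, var)))
  names(lv) <- ga$labels[single]
  list(max_replicate_distance = dmax,
       min_individual_distance = dmin,
       landmark_variance = lv,
       most_variable_landmark = names(lv)[which.max(lv)])
}
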