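# SPHARM-PDM-style shape description. Real spherical-harmonic basis
# (Condon-Shortley-free, orthonormal on the unit sphere), ordered by l
# ascending and m from -l to l; column index j = l^2 + l + m + 1.

#' Real spherical-harmonic basis matrix
#'
#' Evaluates the real orthonormal spherical-harmonic basis up to degree
#' `L` at unit directions `u`.
#'
#' @param u n x 3 matrix of unit vectors.
#' @param L Maximum degree (>= 0).
#' @return n x (L+1)^2 matrix.
#' @export
sph_basis <- function(u, L) {
  u <- as.matrix(u)
  n <- nrow(u)
  z <- pmin(1, pmax(-1, u[, 3]))
  phi <- atan2(u[, 2], u[, 1])
  M <- matrix(NA_real_, n, (L + 1)^2)
  for (l in 0:L) {
    P <- pracma::legendre(l, z)               # (l+1) x n, rows m = 0..l, with CS phase
    if (is.null(dim(P))) P <- matrix(P, nrow = l + 1)
    for (m in 0:l) {
      # strip the Condon-Shortley phase and apply orthonormal normalization
      Nlm <- sqrt((2 * l + 1) / (4 * pi) *
                    exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
      Pm <- (-1)^m * P[m + 1, ]
      if (m == 0) {
        M[, l^2 + l + 1] <- Nlm * Pm
      } else {
        M[, l^2 + l + m + 1] <- sqrt(2) * Nlm * Pm * cos(m * phi)
        M[, l^2 + l - m + 1] <- sqrt(2) * Nlm * Pm * sin(m * phi)
      }
    }
  }
  M
}

# per-vertex area weights of a spherical parametrization (1/3 of adjacent
# face areas on the parameter sphere)
.vertex_area_weights <- function(directions, faces) {
  n <- nrow(directions)
  w <- numeric(n)
  a <- directions[faces[, 1], , drop = FALSE]
  b <- directions[faces[, 2], , drop = FALSE]
  cc <- directions[faces[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- sqrt(rowSums(cr^2)) / 2
  for (j in 1:3) {
    t <- tapply(area, faces[, j], sum)
    w[as.integer(names(t))] <- w[as.integer(names(t))] + t / 3
  }
  w[w <= 0] <- min(w[w > 0])
  w
}

# count spherical triangles whose orientation flips under the map
.flipped_triangles <- function(directions, faces) {
  a <- directions[faces[, 1], , drop = FALSE]
  b <- directions[faces[, 2], , drop = FALSE]
  cc <- directions[faces[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
              b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
              b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  sum(rowSums(a * cr) <= 0)
}

#' Spherical parametrization of a closed genus-0 mesh
#'
#' Maps every vertex to the unit sphere. The initial map is the radial
#' projection about the vertex centroid; if this leaves flipped spherical
#' triangles (non-star-shaped meshes) the map is relaxed by iterated
#' on-sphere Laplacian smoothing until no triangle is inverted.
#'
#' @param mesh A closed genus-0 `otl_mesh` with outward-oriented faces.
#' @param max_relax Maximum relaxation iterations (default 200).
#' @return List with `directions` (n x 3 unit vectors), `flipped`
#'   (residual inverted-triangle count, 0 for a valid map) and
#'   `area_distortion` (ratio of max to min per-vertex parameter area,
#'   1 = perfectly uniform).
#' @export
spherical_parametrize <- function(mesh, max_relax = 200L) {
  validate_genus0(mesh)
  V <- mesh$vertices
  ctr <- colMeans(V)
  U <- sweep(V, 2, ctr)
  nr <- sqrt(rowSums(U^2))
  if (any(nr < 1e-12)) stop("vertex coincides with the mesh centroid")
  U <- U / nr
  flips <- .flipped_triangles(U, mesh$faces)
  if (flips > 0) {
    n <- nrow(V)
    e <- unique(.mesh_edges(mesh))
    A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                              x = 1, dims = c(n, n))
    deg <- Matrix::rowSums(A)
    it <- 0L
    while (flips > 0 && it < max_relax) {
      U <- 0.5 * U + 0.5 * as.matrix(A %*% U) / deg
      U <- U / sqrt(rowSums(U^2))
      flips <- .flipped_triangles(U, mesh$faces)
      it <- it + 1L
    }
  }
  w <- .vertex_area_weights(U, mesh$faces)
  list(directions = U, flipped = flips,
       area_distortion = max(w) / min(w))
}

#' Fit a spherical-harmonic model to a parametrized mesh
#'
#' Per-coordinate weighted least squares of the real spherical-harmonic
#' basis over the mesh vertices; weights are per-vertex areas on the
#' parameter sphere to reduce sampling bias.
#'
#' @param mesh An `otl_mesh`.
#' @param parametrization Output of [spherical_parametrize()] (computed if
#'   `NULL`).
#' @param degree Maximum degree L, with `(L+1)^2` no larger than the
#'   vertex count.
#' @param voxel_spacing Optional provenance metadata (mm) recording the
#'   labelmap spacing a mesh was derived from; does not affect the fit.
#' @return A `spharm_model`: `degree`, `coeffs` ((L+1)^2 x 3),
#'   `parametrization`, `correspondence_rotation` (identity until
#'   [correspondence_align()]), `rmse` (area-weighted RMS reconstruction
#'   residual at the mesh's own parameter points), `voxel_spacing`
#'   metadata.
#' @export
spharm_fit <- function(mesh, parametrization = NULL, degree = 15L,
                       voxel_spacing = NA_real_) {
  if (is.null(parametrization)) parametrization <- spherical_parametrize(mesh)
  U <- parametrization$directions
  n <- nrow(U)
  nb <- (degree + 1)^2
  if (nb > n)
    stop(sprintf("underdetermined system: (L+1)^2 = %d > %d vertices; lower L",
                 nb, n))
  M <- sph_basis(U, degree)
  w <- .vertex_area_weights(U, mesh$faces)
  Mw <- M * sqrt(w)
  Xw <- mesh$vertices * sqrt(w)
  cf <- tryCatch(qr.coef(qr(Mw), Xw), error = function(e)
    stop("spherical-harmonic system could not be solved: ",
         conditionMessage(e)))
  cf[is.na(cf)] <- 0
  res <- mesh$vertices - M %*% cf
  rmse <- sqrt(sum(w * rowSums(res^2)) / sum(w))
  structure(list(degree = as.integer(degree), coeffs = cf,
                 parametrization = parametrization,
                 correspondence_rotation = diag(3),
                 faces = mesh$faces, vertices = mesh$vertices,
                 rmse = rmse, voxel_spacing = voxel_spacing),
            class = "spharm_model")
}

#' @export
print.spharm_model <- function(x, ...) {
  cat(sprintf("spharm_model: degree %d (%d coefficients/axis), rmse %.4g mm\n",
              x$degree, nrow(x$coeffs), x$rmse))
  invisible(x)
}

#' Reconstruction error across a series of degrees
#'
#' Refits the model at each degree with a shared parametrization; the
#' area-weighted RMSE is non-increasing along the (nested) degree ladder.
#'
#' @param mesh An `otl_mesh`.
#' @param degrees Integer vector of degrees, e.g.
#'   `c(1, 2, 3, 4, 5, 10, 15, 25)`.
#' @param parametrization Optional shared parametrization.
#' @return Data frame with `degree` and `rmse`.
#' @export
spharm_degree_series <- function(mesh, degrees = c(1, 2, 3, 4, 5, 10, 15, 25),
                                 parametrization = NULL) {
  if (is.null(parametrization)) parametrization <- spherical_parametrize(mesh)
  data.frame(degree = degrees,
             rmse = vapply(degrees, function(L)
               spharm_fit(mesh, parametrization, L)$rmse, numeric(1)))
}

#' Evaluate a spherical-harmonic model at unit directions
#'
#' @param model A `spharm_model`.
#' @param directions m x 3 unit vectors (before the model's
#'   correspondence rotation).
#' @return m x 3 surface points.
#' @export
spharm_eval <- function(model, directions) {
  u <- as.matrix(directions) %*% t(model$correspondence_rotation)
  sph_basis(u, model$degree) %*% model$coeffs
}

#' Sample a SPHARM model at icosahedral correspondence points
#'
#' Evaluates the harmonic series at the vertex directions of an
#' icosahedral subdivision sphere. Identical `subdivision_level` gives
#' identical sample directions for every model — the correspondence
#' contract of the point-distribution model.
#'
#' @param model A `spharm_model`.
#' @param subdivision_level Icosphere subdivision level (0 gives the bare
#'   12-vertex icosahedron).
#' @return A `pdm_sampling` list: `subdivision_level`, `sample_points`
#'   (sphere directions), `surface_points`, `faces`.
#' @export
pdm_sample <- function(model, subdivision_level = 3L) {
  ico <- icosphere(subdivision_level)
  pts <- spharm_eval(model, ico$vertices)
  structure(list(subdivision_level = as.integer(subdivision_level),
                 sample_points = ico$vertices, surface_points = pts,
                 faces = ico$faces),
            class = "pdm_sampling")
}

#' Align SPHARM parametrizations by their first-order ellipsoids
#'
#' Rotates each model's parameter sphere so the degree-1 (first-order
#' ellipsoid) axes coincide across models, with a deterministic axis
#' ordering and sign convention, then refits the coefficients in the
#' rotated parametrization. Models whose degree-1 part is nearly
#' spherical are left unchanged with a warning.
#'
#' @param models List of `spharm_model` objects of a common degree.
#' @return List of aligned `spharm_model` objects.
#' @export
correspondence_align <- function(models) {
  if (length(models) < 2L) stop("need at least 2 models")
  degs <- vapply(models, function(m) m$degree, integer(1))
  if (length(unique(degs)) != 1L) stop("models must share one degree")
  lapply(models, function(m) {
    A <- t(m$coeffs[2:4, , drop = FALSE])   # 3 coords x (m=-1,0,1)
    G <- A[, c(3, 1, 2)]                    # columns reordered to act on (x,y,z)
    sv <- svd(G)
    if ((sv$d[1] - sv$d[3]) / max(sv$d[1], 1e-300) < 1e-6) {
      warning("degenerate (spherical) degree-1 part; model left unchanged")
      return(m)
    }
    U <- sv$u; V <- sv$v
    for (j in 1:2) {
      if (U[which.max(abs(U[, j])), j] < 0) {
        U[, j] <- -U[, j]; V[, j] <- -V[, j]
      }
    }
    if (det(V) < 0) { U[, 3] <- -U[, 3]; V[, 3] <- -V[, 3] }
    Rp <- t(V)                              # parameter-sphere rotation
    par2 <- m$parametrization
    par2$directions <- par2$directions %*% t(Rp)
    mesh <- otl_mesh(m$vertices, m$faces)
    m2 <- spharm_fit(mesh, par2, m$degree, voxel_spacing = m$voxel_spacing)
    m2$correspondence_rotation <- diag(3)
    m2
  })
}

#' Mean shape of corresponded SPHARM models
#'
#' Pointwise average of the PDM samples; faces come from the subdivision
#' topology.
#'
#' @param models List of corresponded `spharm_model` objects at one common
#'   degree.
#' @param subdivision_level Icosphere subdivision level for the sampling.
#' @return An `otl_mesh` of the mean shape.
#' @export
mean_shape <- function(models, subdivision_level = 3L) {
  degs <- vapply(models, function(m) m$degree, integer(1))
  if (length(unique(degs)) != 1L) stop("mixed degrees: align models first")
  samples <- lapply(models, pdm_sample, subdivision_level = subdivision_level)
  pts <- Reduce(`+`, lapply(samples, function(s) s$surface_points)) /
    length(samples)
  otl_mesh(pts, samples[[1]]$faces)
}
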