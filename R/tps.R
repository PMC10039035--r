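# 3D thin-plate-spline machinery. Kernel U(r) = r (the 3D biharmonic
# choice). With this kernel w'Kw is <= 0 on the affine-orthogonal subspace,
# so the non-negative bending energy is -sum_d w_d' K w_d.

.tps_kernel <- function(A, B) {
  # |a_i - b_j| distance matrix, computed from explicit differences (the
  # expanded-square shortcut loses ~8 digits for nearby points)
  m <- nrow(A)
  out <- matrix(0, m, nrow(B))
  for (j in seq_len(nrow(B)))
    out[, j] <- sqrt((A[, 1] - B[j, 1])^2 + (A[, 2] - B[j, 2])^2 +
                       (A[, 3] - B[j, 3])^2)
  out
}

#' Fit a 3D thin-plate-spline warp
#'
#' Exact interpolating TPS with kernel U(r) = r mapping `source` landmarks
#' onto `target` landmarks. A small Tikhonov regularization (`lambda`) on
#' the kernel matrix keeps near-degenerate (e.g. coplanar) configurations
#' solvable.
#'
#' @param source,target k x 3 matrices of corresponding landmarks (k >= 4).
#' @param lambda Tikhonov regularization added to the kernel diagonal for
#'   near-degenerate (e.g. coplanar) configurations; `NULL` (default)
#'   solves the exact interpolation system and falls back to 1e-8 only
#'   when the system is numerically singular.
#' @return A `tps_warp` object with `source_landmarks`, `target_landmarks`,
#'   `weights` (k x 3 non-affine coefficients), `affine` (4 x 3: intercept
#'   row then linear part) and `bending_energy`.
#' @export
tps_fit <- function(source, target, lambda = NULL) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (!all(dim(source) == dim(target)))
    stop("source and target must have identical dimensions")
  k <- nrow(source)
  if (k < 4L) stop("need at least 4 landmarks")
  dup <- which(as.matrix(dist(source)) < 1e-12 &
                 upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  if (nrow(dup))
    stop("duplicated source points: ",
         paste(apply(dup, 1, paste, collapse = "/"), collapse = ", "))
  K <- .tps_kernel(source, source)
  P <- cbind(1, source)
  rhs <- rbind(target, matrix(0, 4, 3))
  assemble <- function(lam) rbind(cbind(K + lam * diag(k), P),
                                  cbind(t(P), matrix(0, 4, 4)))
  sol <- NULL
  if (is.null(lambda)) {
    sol <- tryCatch(solve(assemble(0), rhs), error = function(e) NULL)
    lambda <- if (is.null(sol)) 1e-8 else 0
  }
  if (is.null(sol))
    sol <- tryCatch(solve(assemble(lambda), rhs), error = function(e)
      stop("singular TPS system: ", conditionMessage(e)))
  # one step of iterative refinement tightens the interpolation to
  # near machine precision
  L <- assemble(lambda)
  sol <- sol + solve(L, rhs - L %*% sol)
  W <- sol[1:k, , drop = FALSE]
  A <- sol[(k + 1):(k + 4), , drop = FALSE]
  be <- -sum(vapply(1:3, function(d) sum(W[, d] * (K %*% W[, d])), numeric(1)))
  structure(list(source_landmarks = source, target_landmarks = target,
                 weights = W, affine = A, bending_energy = max(0, be),
                 lambda = lambda),
            class = "tps_warp")
}

#' @export
print.tps_warp <- function(x, ...) {
  cat(sprintf("tps_warp: %d landmarks, bending energy %.6g\n",
              nrow(x$source_landmarks), x$bending_energy))
  invisible(x)
}

#' Apply a fitted TPS warp to query points
#'
#' @param warp A `tps_warp` from [tps_fit()].
#' @param points m x 3 matrix of query points.
#' @return m x 3 matrix of warped points.
#' @export
tps_apply <- function(warp, points) {
  Q <- as.matrix(points)
  if (is.null(dim(Q))) Q <- matrix(Q, 1)
  U <- .tps_kernel(Q, warp$source_landmarks)
  cbind(1, Q) %*% warp$affine + U %*% warp$weights
}

#' Warp a triangle mesh through a TPS
#'
#' Every vertex is mapped through the spline; face topology is unchanged.
#'
#' @param warp A `tps_warp`.
#' @param mesh An `otl_mesh` (see [otl_mesh()]).
#' @return The warped mesh.
#' @export
warp_mesh <- function(warp, mesh) {
  stopifnot(inherits(mesh, "otl_mesh"))
  out <- mesh
  out$vertices <- tps_apply(warp, mesh$vertices)
  out
}

#' Bending-energy matrix of a reference configuration
#'
#' Upper-left k x k block of the inverted TPS system, sign-fixed so that
#' the bending energy of a target configuration `Y` relative to the
#' reference is `sum_d y_d' B y_d >= 0` (zero iff `Y` is an affine image
#' of the reference).
#'
#' @param reference k x 3 reference landmarks.
#' @param lambda Kernel regularization (default 1e-8).
#' @return k x k bending-energy matrix.
#' @export
bending_energy_matrix <- function(reference, lambda = 1e-8) {
  reference <- as.matrix(reference)
  k <- nrow(reference)
  K <- .tps_kernel(reference, reference)
  P <- cbind(1, reference)
  L <- rbind(cbind(K + lambda * diag(k), P), cbind(t(P), matrix(0, 4, 4)))
  Li <- solve(L)
  B <- -Li[1:k, 1:k]
  (B + t(B)) / 2
}

.bending_energy_of <- function(B, Y) {
  sum(vapply(1:3, function(d) sum(Y[, d] * (B %*% Y[, d])), numeric(1)))
}

#' Resample a polyline to equidistant points
#'
#' Output points lie on the input polyline with equal consecutive
#' arc-length spacing; the endpoints are preserved.
#'
#' @param curve_points Ordered m x 3 matrix of polyline vertices (m >= 2).
#' @param n_out Number of output points (>= 2).
#' @return n_out x 3 matrix.
#' @export
resample_equidistant <- function(curve_points, n_out) {
  X <- as.matrix(curve_points)
  m <- nrow(X)
  if (m < 2L) stop("need at least 2 curve points")
  if (n_out < 2L) stop("n_out must be >= 2")
  seg <- sqrt(rowSums((X[-1, , drop = FALSE] - X[-m, , drop = FALSE])^2))
  total <- sum(seg)
  if (total <= 0) stop("zero-length curve")
  s <- c(0, cumsum(seg))
  target <- seq(0, total, length.out = n_out)
  out <- matrix(NA_real_, n_out, 3)
  j <- 1L
  for (i in seq_len(n_out)) {
    t0 <- min(target[i], total)
    while (j < m && s[j + 1] < t0) j <- j + 1L
    if (seg[j] <= 0) { out[i, ] <- X[j, ]; next }
    a <- (t0 - s[j]) / seg[j]
    out[i, ] <- (1 - a) * X[j, ] + a * X[j + 1, ]
  }
  out[1, ] <- X[1, ]; out[n_out, ] <- X[m, ]
  out
}

# curve tangents by central differences (one-sided at the ends)
.curve_tangents <- function(P) {
  m <- nrow(P)
  T <- matrix(0, m, 3)
  if (m >= 2) {
    T[1, ] <- P[2, ] - P[1, ]
    T[m, ] <- P[m, ] - P[m - 1, ]
  }
  if (m >= 3) T[2:(m - 1), ] <- P[3:m, ] - P[1:(m - 2), ]
  nr <- sqrt(rowSums(T^2))
  if (any(nr < 1e-14))
    stop("tangent undefined: coincident neighboring curve points")
  T / nr
}

.closest_on_polyline <- function(p, X) {
  # closest point to p on polyline X (m x 3)
  m <- nrow(X)
  best <- X[1, ]; bd <- sum((p - X[1, ])^2)
  for (j in seq_len(m - 1L)) {
    a <- X[j, ]; b <- X[j + 1L, ]
    ab <- b - a
    t <- sum((p - a) * ab) / max(sum(ab^2), 1e-300)
    t <- min(1, max(0, t))
    q <- a + t * ab
    d <- sum((p - q)^2)
    if (d < bd) { bd <- d; best <- q }
  }
  best
}

#' Slide semilandmarks along curve tangents minimizing bending energy
#'
#' Iteratively displaces each specimen's semilandmarks along their local
#' curve tangent directions so as to minimize the thin-plate-spline
#' bending energy relative to the current consensus (single landmarks and
#' curve endpoints never move). After the linearized tangential update the
#' slid points are snapped back onto the specimen's curve polyline; if a
#' specimen's update would increase its bending energy the update is
#' rejected, so the within-pass energy trace is non-increasing by
#' construction. The set is re-superimposed after every pass.
#'
#' @param aligned An `aligned_shapes` object from [gpa()] whose metadata
#'   identifies semilandmark curves.
#' @param max_iter Maximum sliding passes (default 5).
#' @param tol Relative energy-change stopping tolerance (default 1e-6).
#' @param anchors_fixed Keep first/last point of every curve fixed
#'   (default `TRUE`).
#' @return The slid (and re-superimposed) `aligned_shapes` object with an
#'   `energy_trace` data frame (pass, energy before/after measured against
#'   that pass's consensus).
#' @export
slide_semilandmarks <- function(aligned, max_iter = 5L, tol = 1e-6,
                                anchors_fixed = TRUE) {
  stopifnot(inherits(aligned, "aligned_shapes"))
  crv_ids <- unique(aligned$curve[!is.na(aligned$curve) & aligned$role == "semi"])
  if (!length(crv_ids)) return(aligned)
  curves <- lapply(crv_ids, function(cv) which(aligned$curve %in% cv &
                                                 aligned$role == "semi"))
  names(curves) <- crv_ids
  n <- dim(aligned$coords)[1]; k <- dim(aligned$coords)[2]

  # indices allowed to slide
  sliders <- integer(0)
  for (cv in crv_ids) {
    idx <- curves[[cv]]
    if (anchors_fixed && length(idx) > 2L) idx <- idx[-c(1L, length(idx))]
    if (!anchors_fixed || length(idx) > 2L) sliders <- c(sliders, idx)
  }
  sliders <- sort(unique(sliders))
  m <- length(sliders)
  if (!m) return(aligned)

  trace <- data.frame(pass = integer(0), energy_before = numeric(0),
                      energy_after = numeric(0))
  for (pass in seq_len(max_iter)) {
    cons <- aligned$consensus
    B <- bending_energy_matrix(cons)
    e_before <- 0; e_after <- 0
    for (i in seq_len(n)) {
      Y <- aligned$coords[i, , ]
      e0 <- .bending_energy_of(B, Y)
      # tangents at current semilandmark positions
      U <- matrix(0, k, 3)
      for (cv in crv_ids) {
        idx <- curves[[cv]]
        U[idx, ] <- .curve_tangents(Y[idx, , drop = FALSE])
      }
      # linearized tangential minimization: H t = -g on slider rows
      G <- B %*% Y                                     # k x 3 gradient/2
      g <- rowSums(U[sliders, , drop = FALSE] * G[sliders, , drop = FALSE])
      H <- B[sliders, sliders, drop = FALSE] *
        (U[sliders, , drop = FALSE] %*% t(U[sliders, , drop = FALSE]))
      tvec <- tryCatch(
        solve(H + 1e-10 * diag(m), -g),
        error = function(e) rep(0, m))
      Ynew <- Y
      Ynew[sliders, ] <- Y[sliders, ] + tvec * U[sliders, , drop = FALSE]
      # snap back onto the specimen's curve polyline
      for (cv in crv_ids) {
        idx <- curves[[cv]]
        sl <- intersect(idx, sliders)
        if (!length(sl)) next
        poly <- Y[idx, , drop = FALSE]
        for (j in sl) Ynew[j, ] <- .closest_on_polyline(Ynew[j, ], poly)
      }
      e1 <- .bending_energy_of(B, Ynew)
      if (e1 <= e0) {
        aligned$coords[i, , ] <- Ynew
      } else e1 <- e0                                   # reject worsening update
      e_before <- e_before + e0
      e_after <- e_after + e1
    }
    trace <- rbind(trace, data.frame(pass = pass, energy_before = e_before,
                                     energy_after = e_after))
    # re-superimpose and update consensus
    cfgs <- lapply(seq_len(n), function(i) aligned$coords[i, , ])
    re <- gpa(cfgs, scale = aligned$scale)
    aligned$coords[] <- re$coords
    aligned$consensus <- re$consensus
    if (e_before <= 0 || (e_before - e_after) / max(e_before, 1e-300) < tol)
      break
  }
  aligned$energy_trace <- trace
  aligned
}
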