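# Shared helpers and independent oracles used across the suite.

random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rotation_axis_angle <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# quasi-uniform directions on the sphere (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

# Independent OPA oracle: minimizes the unit-size residual 2 - 2 tr(R M)
# over rotations by searching axis directions; for a fixed axis the best
# angle has the closed form max_theta A cos + B sin = sqrt(A^2 + B^2).
# Never uses an SVD.
opa_grid_oracle <- function(X, Y, n_axes = 20000) {
  cX <- scale(X, scale = FALSE); cX <- cX / sqrt(sum(cX^2))
  cY <- scale(Y, scale = FALSE); cY <- cY / sqrt(sum(cY^2))
  M <- crossprod(cY, cX)
  trM <- sum(diag(M))
  mc <- c(M[3, 2] - M[2, 3], M[1, 3] - M[3, 1], M[2, 1] - M[1, 2])
  axes <- fibonacci_sphere(n_axes)
  aMa <- rowSums((axes %*% M) * axes)
  A <- trM - aMa
  B <- as.numeric(axes %*% mc)
  best_tr <- function(aMa, A, B) aMa + sqrt(A^2 + B^2)
  vals <- best_tr(aMa, A, B)
  # local refinement on the best axis (spherical coordinates)
  a0 <- axes[which.max(vals), ]
  f <- function(p) {
    a <- c(cos(p[2]) * cos(p[1]), cos(p[2]) * sin(p[1]), sin(p[2]))
    aMa1 <- sum((a %*% M) * a)
    -(aMa1 + sqrt((trM - aMa1)^2 + sum(a * mc)^2))
  }
  p0 <- c(atan2(a0[2], a0[1]), asin(max(-1, min(1, a0[3]))))
  op <- optim(p0, f, method = "Nelder-Mead",
              control = list(reltol = 1e-14, maxit = 2000))
  tr_best <- max(max(vals), -op$value)
  sqrt(max(0, 2 - 2 * tr_best))
}

# Independent TPS solver: eliminates the affine-orthogonality constraint
# with an explicit null-space basis instead of solving the bordered
# system.
tps_nullspace_oracle <- function(X, Y, lambda = 0, refine = 2) {
  k <- nrow(X)
  K <- as.matrix(dist(X)) + if (lambda > 0) lambda * diag(k) else 0
  P <- cbind(1, X)
  Qfull <- qr.Q(qr(P), complete = TRUE)
  Q2 <- Qfull[, 5:k, drop = FALSE]
  solve_once <- function(Yv) {
    W <- matrix(0, k, 3)
    for (d in 1:3) {
      cvec <- solve(crossprod(Q2, K %*% Q2), crossprod(Q2, Yv[, d]))
      W[, d] <- Q2 %*% cvec
    }
    A <- qr.solve(P, Yv - K %*% W)
    list(weights = W, affine = A)
  }
  sol <- solve_once(Y)
  # refine by re-solving on the interpolation residual (same method)
  for (r in seq_len(refine)) {
    res <- Y - K %*% sol$weights - P %*% sol$affine
    corr <- solve_once(res)
    sol$weights <- sol$weights + corr$weights
    sol$affine <- sol$affine + corr$affine
  }
  sol
}

# Dense-grid total-least-squares plane oracle with local refinement
plane_grid_oracle <- function(points, n_dirs = 100000) {
  X <- scale(as.matrix(points), scale = FALSE)
  C <- crossprod(X)
  dirs <- fibonacci_sphere(n_dirs)
  ss <- rowSums((dirs %*% C) * dirs)
  d0 <- dirs[which.min(ss), ]
  f <- function(p) {
    a <- c(cos(p[2]) * cos(p[1]), cos(p[2]) * sin(p[1]), sin(p[2]))
    sum((a %*% C) * a)
  }
  p0 <- c(atan2(d0[2], d0[1]), asin(max(-1, min(1, d0[3]))))
  op <- optim(p0, f, method = "Nelder-Mead",
              control = list(reltol = 1e-15, maxit = 4000))
  p <- op$par
  c(cos(p[2]) * cos(p[1]), cos(p[2]) * sin(p[1]), sin(p[2]))
}

# Ellipsoid axes by PCA moment fit of near-surface samples
fit_ellipsoid_axes <- function(points) {
  sort(sqrt(eigen(cov(points))$values), decreasing = TRUE)
}

# small triangulated torus (genus 1) for topology negative controls
torus_mesh <- function(nu = 12, nv = 8, R = 2, r = 0.6) {
  iu <- rep(seq_len(nu), each = nv); iv <- rep(seq_len(nv), nu)
  u <- 2 * pi * (iu - 1) / nu; v <- 2 * pi * (iv - 1) / nv
  V <- cbind((R + r * cos(v)) * cos(u), (R + r * cos(v)) * sin(u),
             r * sin(v))
  idx <- function(i, j) ((i - 1) %% nu) * nv + ((j - 1) %% nv) + 1
  F <- NULL
  for (i in seq_len(nu)) for (j in seq_len(nv)) {
    a <- idx(i, j); b <- idx(i + 1, j); c <- idx(i + 1, j + 1); d <- idx(i, j + 1)
    F <- rbind(F, c(a, b, c), c(a, c, d))
  }
  otl_mesh(V, F)
}

# quick accessors for generated populations
pop_configs <- function(pop) lapply(pop, `[[`, "config")
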