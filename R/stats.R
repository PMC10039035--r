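# PCA of Procrustes coordinates, OLS batteries, two-block PLS integration
# and covariance-ratio modularity tests.

#' Principal component analysis of aligned shape coordinates
#'
#' Centered SVD of the flattened (n x 3k) coordinates. Loadings are
#' sign-fixed so each component's largest-magnitude element is positive,
#' making PC scores reproducible across runs.
#'
#' @param block An `aligned_shapes` object (or view from
#'   [subset_blocks()]), or an n x p numeric matrix.
#' @return A `shape_pca` object with `scores`, `loadings`, `eigenvalues`
#'   (descending, summing to the total Procrustes variance) and
#'   `total_variance`.
#' @export
shape_pca <- function(block) {
  X <- if (inherits(block, "aligned_shapes")) flatten_shapes(block) else as.matrix(block)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 specimens")
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  r <- sum(sv$d > max(sv$d) * 1e-12)
  d <- sv$d[seq_len(r)]
  U <- sv$u[, seq_len(r), drop = FALSE]
  V <- sv$v[, seq_len(r), drop = FALSE]
  # sign convention: largest-|.| loading element positive
  for (j in seq_len(r)) {
    s <- sign(V[which.max(abs(V[, j])), j])
    if (s < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
  }
  scores <- U %*% diag(d, r, r)
  colnames(scores) <- colnames(V) <- paste0("PC", seq_len(r))
  rownames(scores) <- rownames(X)
  structure(list(scores = scores, loadings = V,
                 eigenvalues = d^2 / (n - 1),
                 total_variance = sum(Xc^2) / (n - 1)),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  pv <- x$eigenvalues / sum(x$eigenvalues)
  cat(sprintf("shape_pca: %d components; PC1 explains %.1f%% of variance\n",
              length(x$eigenvalues), 100 * pv[1]))
  invisible(x)
}

#' Simple ordinary least-squares regression
#'
#' Fits `y ~ x` by [stats::lm()] and reports slope, intercept, R-squared
#' and the two-sided p-value from the F-test of zero slope.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return An `ols_fit` list: `slope`, `intercept`, `r_squared`,
#'   `f_statistic`, `p_value`, `n`.
#' @export
ols_regress <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n < 3L || length(y) != n) stop("need matched x, y with n >= 3")
  if (var(x) <= 0) stop("constant predictor")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))   # perfect fits are legitimate here
  fstat <- unname(sm$fstatistic)
  p <- if (is.null(fstat)) 1 else pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 f_statistic = if (is.null(fstat)) NA_real_ else fstat[1],
                 p_value = max(p, .Machine$double.xmin),
                 n = n),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("ols_fit: slope %.4g, R2 %.3f, p %.3g (n = %d)\n",
              x$slope, x$r_squared, x$p_value, x$n))
  invisible(x)
}

# resolve a battery subset (labels) into columns/statistic
.battery_stat <- function(aligned, labels, statistic) {
  idx <- match(labels, aligned$labels)
  if (anyNA(idx))
    stop("unknown labels: ", paste(labels[is.na(idx)], collapse = ", "))
  if (statistic == "pc1") {
    v <- aligned
    v$coords <- aligned$coords[, idx, , drop = FALSE]
    v$labels <- aligned$labels[idx]
    shape_pca(v)$scores[, 1]
  } else if (statistic == "log_centroid_size") {
    n <- dim(aligned$coords)[1]
    # centroid size on the pre-scaling coordinates: undo the unit-size
    # scaling applied during GPA so size reflects the original specimen
    s <- if (isTRUE(aligned$scale)) aligned$centroid_sizes else rep(1, n)
    log(vapply(seq_len(n), function(i)
      centroid_size(aligned$coords[i, idx, , drop = FALSE][1, , ]) * s[i],
      numeric(1)))
  } else stop("unknown statistic: ", statistic)
}

#' Run a battery of OLS regressions on shape or size summaries
#'
#' Each row of `battery` names a response subset, a predictor subset and a
#' statistic (`"pc1"` or `"log_centroid_size"`); subsets are lists of
#' landmark labels resolved against the jointly aligned set. Rows that
#' fail (e.g. empty subsets) are recorded with an error message and the
#' battery continues.
#'
#' @param aligned An `aligned_shapes` object from [gpa()].
#' @param battery Data frame with columns `model`, `response`, `predictor`
#'   (labels of entries in `subsets`), `statistic`; or `NULL` for the
#'   default 26-model battery from [default_battery()].
#' @param subsets Named list mapping subset names to landmark label
#'   vectors; defaults to the package's standard subsets.
#' @return Data frame with one row per model: estimate, R-squared, F, p
#'   and n (or an error message).
#' @export
regression_battery <- function(aligned, battery = NULL, subsets = NULL) {
  if (is.null(battery)) battery <- default_battery()
  if (is.null(subsets)) subsets <- default_battery_subsets()
  out <- lapply(seq_len(nrow(battery)), function(i) {
    row <- battery[i, ]
    res <- tryCatch({
      yl <- subsets[[row$response]]
      xl <- subsets[[row$predictor]]
      if (is.null(yl) || is.null(xl)) stop("unresolvable subset")
      y <- .battery_stat(aligned, yl, row$statistic)
      x <- .battery_stat(aligned, xl, row$statistic)
      f <- ols_regress(x, y)
      data.frame(model = row$model, response = row$response,
                 predictor = row$predictor, statistic = row$statistic,
                 slope = f$slope, r_squared = f$r_squared,
                 f_statistic = f$f_statistic, p_value = f$p_value,
                 n = f$n, error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(model = row$model, response = row$response,
                 predictor = row$predictor, statistic = row$statistic,
                 slope = NA_real_, r_squared = NA_real_,
                 f_statistic = NA_real_, p_value = NA_real_,
                 n = NA_integer_, error = conditionMessage(e),
                 stringsAsFactors = FALSE))
    res
  })
  do.call(rbind, out)
}

#' Landmark subsets backing the default regression battery
#'
#' Combines the block splits of the six analysis sets with the
#' single-landmark centroid-size subsets.
#'
#' @return Named list of landmark label vectors.
#' @export
default_battery_subsets <- function() {
  scheme <- otolith_scheme()
  pick <- function(set_id, block) {
    s <- landmark_set(set_id)
    names(s$blocks)[s$blocks == block]
  }
  subs <- list(
    set1_bony = pick(1, "bony"), set1_membranous = pick(1, "membranous"),
    set2_bony = pick(2, "bony"), set2_membranous = pick(2, "membranous"),
    set3_bony = pick(3, "bony"), set3_membranous = pick(3, "membranous"),
    set4_bony = pick(4, "bony"), set4_membranous = pick(4, "membranous"),
    set5_bony = pick(5, "bony"), set5_membranous = pick(5, "membranous"),
    gu_bony = paste0("LM", 1:6),
    gu_membranous = c(paste0("LM", c(11:13, 17:19)),
                      scheme$label[!is.na(scheme$curve) &
                                     scheme$curve %in% c("SemiLM3", "SemiLM4")]),
    gs_bony = c(paste0("LM", 7:10),
                scheme$label[!is.na(scheme$curve) &
                               scheme$curve %in% c("SemiLM1", "SemiLM2")]),
    gs_membranous = c(paste0("LM", c(14:16, 20:22)),
                      scheme$label[!is.na(scheme$curve) & scheme$curve == "SemiLM5"]),
    gu_bony_singles = paste0("LM", 1:6),
    gu_membranous_singles = paste0("LM", c(11:13, 17:19)),
    gs_bony_singles = paste0("LM", 7:10),
    gs_membranous_singles = paste0("LM", c(14:16, 20:22)),
    utricular_macula_full = c(paste0("LM", 17:19),
                              scheme$label[!is.na(scheme$curve) & scheme$curve == "SemiLM4"]),
    saccular_macula_full = c(paste0("LM", 20:22),
                             scheme$label[!is.na(scheme$curve) & scheme$curve == "SemiLM5"])
  )
  c(subs, centroid_size_subsets())
}

#' Default regression battery (11 shape + 15 size models)
#'
#' Eleven PC1-on-PC1 models (bony response, membranous predictor) across
#' the analysis sets and organ-wise splits, and fifteen log-centroid-size
#' models pairing bony with membranous single-landmark subsets.
#'
#' @return Data frame with columns `model`, `response`, `predictor`,
#'   `statistic`.
#' @export
default_battery <- function() {
  pc1 <- data.frame(
    model = paste0("shape_", c("set1", "set2", "set3", "set4", "set5",
                               "gu", "gs", "gu_singles", "gs_singles",
                               "utricular_macula", "saccular_macula")),
    response = c("set1_bony", "set2_bony", "set3_bony", "set4_bony",
                 "set5_bony", "gu_bony", "gs_bony", "gu_bony_singles",
                 "gs_bony_singles", "gu_bony_singles", "gs_bony_singles"),
    predictor = c("set1_membranous", "set2_membranous", "set3_membranous",
                  "set4_membranous", "set5_membranous", "gu_membranous",
                  "gs_membranous", "gu_membranous_singles",
                  "gs_membranous_singles", "utricular_macula_full",
                  "saccular_macula_full"),
    statistic = "pc1", stringsAsFactors = FALSE)
  cs_pairs <- rbind(
    expand.grid(response = c("bony_utricle", "bony_utricle_reduced"),
                predictor = c("membranous_utricle", "utricular_macula"),
                stringsAsFactors = FALSE),
    expand.grid(response = c("bony_saccule", "spherical_recess"),
                predictor = c("membranous_saccule", "saccular_macula"),
                stringsAsFactors = FALSE),
    expand.grid(response = "bony_all",
                predictor = c("membranous_utricle", "utricular_macula",
                              "membranous_saccule", "saccular_macula"),
                stringsAsFactors = FALSE),
    data.frame(response = c("bony_utricle", "bony_saccule", "spherical_recess"),
               predictor = c("membranous_saccule", "membranous_utricle",
                             "utricular_macula"), stringsAsFactors = FALSE))
  cs <- data.frame(model = sprintf("size_%02d", seq_len(nrow(cs_pairs))),
                   response = cs_pairs$response, predictor = cs_pairs$predictor,
                   statistic = "log_centroid_size", stringsAsFactors = FALSE)
  rbind(pc1, cs)
}

.as_block_matrix <- function(x) {
  if (inherits(x, "aligned_shapes")) flatten_shapes(x) else as.matrix(x)
}

#' Two-block partial least squares test of integration
#'
#' Singular value decomposition of the cross-block covariance of the
#' centered blocks. The integration statistic r-PLS is the Pearson
#' correlation of the first-pair block scores; its permutation null is
#' built by randomly permuting the specimen rows of the second block.
#' p-values use the add-one estimator `(1 + #{perm >= obs}) / (n_perm + 1)`
#' (upper tail); the effect size z standardizes the observed statistic
#' against the permutation distribution.
#'
#' @param block_a,block_b n x p / n x q matrices (or `aligned_shapes`
#'   views), rows matched by specimen.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed for the permutation stream.
#' @return An `integration_result` list: `r_pls`, `effect_size_z`,
#'   `p_value`, `n_permutations`, `left_vectors`, `right_vectors`,
#'   `singular_value`, `perm_summary`, `seed`.
#' @export
two_block_pls <- function(block_a, block_b, n_perm = 10000L, seed = 1L) {
  Xa <- .as_block_matrix(block_a); Xb <- .as_block_matrix(block_b)
  n <- nrow(Xa)
  if (n < 4L || nrow(Xb) != n) stop("need row-matched blocks with n >= 4")
  if (n_perm < 99L) warning("fewer than 99 permutations is unreliable")
  Xa <- sweep(Xa, 2, colMeans(Xa)); Xb <- sweep(Xb, 2, colMeans(Xb))
  if (sum(Xa^2) == 0 || sum(Xb^2) == 0) stop("zero-variance block")

  # n-space reduction: Xa' Xb = Qa (Ra Rb') Qb'
  qa <- qr(t(Xa)); qb <- qr(t(Xb))
  Qa <- qr.Q(qa); Ra <- qr.R(qa)       # t(Xa) = Qa Ra, Qa is p x n
  Qb <- qr.Q(qb); Rb <- qr.R(qb)
  # account for column pivoting absence: qr without pivoting here
  M <- Ra %*% t(Rb)
  sv <- svd(M)
  ua <- Qa %*% sv$u[, 1]
  vb <- Qb %*% sv$v[, 1]
  Fa <- Xa %*% Qa                       # n x n score factors
  Fb <- Xb %*% Qb
  fa <- Fa %*% sv$u[, 1]
  fb <- Fb %*% sv$v[, 1]
  r_obs <- as.numeric(cor(fa, fb))
  if (r_obs < 0) { vb <- -vb; fb <- -fb; r_obs <- -r_obs }

  set.seed(seed)
  rperm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    pidx <- sample.int(n)
    # permuted block_b: rows of Xb permuted => Rb columns permuted
    Mp <- Ra %*% t(Rb[, pidx, drop = FALSE])
    svp <- svd(Mp)
    fap <- Fa %*% svp$u[, 1]
    fbp <- Fb[pidx, , drop = FALSE] %*% svp$v[, 1]
    rperm[b] <- abs(as.numeric(cor(fap, fbp)))
  }
  p <- (1 + sum(rperm >= r_obs)) / (n_perm + 1)
  z <- if (sd(rperm) > 0) (r_obs - mean(rperm)) / sd(rperm) else 0
  structure(list(r_pls = r_obs, effect_size_z = z, p_value = p,
                 n_permutations = n_perm,
                 left_vectors = ua, right_vectors = vb,
                 singular_value = sv$d[1],
                 scores_a = as.numeric(fa), scores_b = as.numeric(fb),
                 perm_summary = c(mean = mean(rperm), sd = sd(rperm),
                                  q95 = unname(quantile(rperm, 0.95))),
                 seed = seed, n = n),
            class = "integration_result")
}

#' @export
print.integration_result <- function(x, ...) {
  cat(sprintf("2B-PLS: r-PLS %.3f, z %.2f, p %.4g (%d permutations)\n",
              x$r_pls, x$effect_size_z, x$p_value, x$n_permutations))
  invisible(x)
}

# per-landmark squared-covariance table for CR
.cr_tables <- function(X, coord_dim) {
  n <- nrow(X)
  S <- crossprod(sweep(X, 2, colMeans(X))) / (n - 1)
  P <- ncol(X)
  K <- P / coord_dim
  S2 <- S^2
  # T[i,j] = sum of squared entries of the coord_dim x coord_dim block (i,j)
  grp <- rep(seq_len(K), each = coord_dim)
  Tm <- rowsum(t(rowsum(S2, grp)), grp)
  list(T = Tm, K = K)
}

.cr_value <- function(tab, modA) {
  # within-module norms exclude the within-landmark diagonal blocks, which
  # keeps CR invariant to the orientation of the coordinate frame
  A <- modA; B <- setdiff(seq_len(tab$K), modA)
  cross <- sum(tab$T[A, B])
  wA <- sum(tab$T[A, A]) - sum(diag(tab$T)[A])
  wB <- sum(tab$T[B, B]) - sum(diag(tab$T)[B])
  if (wA <= 0 || wB <= 0) return(NA_real_)
  sqrt(cross) / sqrt(sqrt(wA) * sqrt(wB))
}

#' Covariance-ratio test of modularity
#'
#' CR is the Frobenius norm of the between-module covariance relative to
#' the within-module covariances with the within-landmark diagonal blocks
#' excluded (for `coord_dim = 1` this is the ordinary diagonal exclusion;
#' the block form keeps CR invariant to rotations of the coordinate
#' frame). Values below 1 indicate modular structure. The permutation
#' null reassigns whole landmarks (all their coordinates together) to
#' modules of the original sizes; p is the fraction of permuted CR values
#' at or below the observed one (add-one estimator, small CR = modular).
#'
#' @param block_a,block_b Matrices (or `aligned_shapes` views) whose
#'   columns are grouped in consecutive `coord_dim`-tuples per landmark.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param coord_dim Coordinates per landmark (default 3).
#' @return A `modularity_result` list: `cr`, `p_value`, `effect_size_z`,
#'   `n_permutations`, `module_assignment`, `seed`.
#' @export
modularity_cr <- function(block_a, block_b, n_perm = 10000L, seed = 1L,
                          coord_dim = 3L) {
  Xa <- .as_block_matrix(block_a); Xb <- .as_block_matrix(block_b)
  if (nrow(Xa) != nrow(Xb)) stop("blocks must be row-matched")
  if (ncol(Xa) %% coord_dim || ncol(Xb) %% coord_dim)
    stop("column count must be a multiple of coord_dim")
  kA <- ncol(Xa) / coord_dim; kB <- ncol(Xb) / coord_dim
  if (kA < 2L || kB < 2L) stop("each module needs at least 2 landmarks")
  X <- cbind(Xa, Xb)
  tab <- .cr_tables(X, coord_dim)
  modA <- seq_len(kA)
  cr_obs <- .cr_value(tab, modA)
  set.seed(seed)
  crp <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    crp[b] <- .cr_value(tab, sample.int(tab$K, kA))
  }
  crp <- crp[is.finite(crp)]
  p <- (1 + sum(crp <= cr_obs)) / (length(crp) + 1)
  z <- if (sd(crp) > 0) (cr_obs - mean(crp)) / sd(crp) else 0
  structure(list(cr = cr_obs, p_value = p, effect_size_z = z,
                 n_permutations = n_perm,
                 module_assignment = rep(c("a", "b"), c(kA, kB)),
                 perm_summary = c(mean = mean(crp), sd = sd(crp)),
                 seed = seed, n = nrow(X)),
            class = "modularity_result")
}

#' @export
print.modularity_result <- function(x, ...) {
  cat(sprintf("modularity CR: %.3f, z %.2f, p %.4g (%d permutations)\n",
              x$cr, x$effect_size_z, x$p_value, x$n_permutations))
  invisible(x)
}

#' Wilcoxon rank-sum comparison of two samples
#'
#' Midrank rank-sum test via [stats::wilcox.test()]: exact enumeration
#' when both samples have at most 8 untied observations, otherwise the
#' normal approximation with continuity correction.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @param continuity Apply the continuity correction in the normal
#'   approximation (default `TRUE`).
#' @return List with `statistic` (rank-sum W) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(sample_a, sample_b, continuity = TRUE) {
  a <- as.numeric(sample_a); b <- as.numeric(sample_b)
  if (!length(a) || !length(b)) stop("samples must be non-empty")
  if (length(unique(c(a, b))) == 1L) {
    warning("all values identical across both samples")
    return(list(statistic = length(a) * length(b) / 2, p_value = 1))
  }
  exact <- length(a) <= 8L && length(b) <= 8L &&
    !anyDuplicated(c(a, b))
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact,
                                     correct = continuity))
  list(statistic = unname(wt$statistic), p_value = min(1, wt$p.value))
}
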