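# Triangle-mesh container and plain-text OBJ/PLY I/O.

#' Construct a triangle mesh
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices,
#'   consistently (counter-clockwise, outward) oriented for closed meshes.
#' @return An object of class `otl_mesh`.
#' @export
otl_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be n x 3")
  if (ncol(faces) != 3L) stop("faces must be m x 3")
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "otl_mesh")
}

#' @export
print.otl_mesh <- function(x, ...) {
  cat(sprintf("otl_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# undirected edge list (2-column, each row sorted)
.mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  t(apply(e, 1, sort))
}

#' Validate closed genus-0 topology
#'
#' Checks that every edge is shared by exactly two faces (closed, manifold)
#' and that the Euler characteristic V - E + F equals 2 (genus 0).
#'
#' @param mesh An `otl_mesh`.
#' @param stop_on_fail Raise an error on failure (default `TRUE`).
#' @return Invisibly, a list with `closed`, `euler`, `genus0`.
#' @export
validate_genus0 <- function(mesh, stop_on_fail = TRUE) {
  e <- .mesh_edges(mesh)
  key <- paste(e[, 1], e[, 2])
  tab <- table(key)
  closed <- all(tab == 2L)
  V <- nrow(mesh$vertices); Fc <- nrow(mesh$faces); E <- length(tab)
  euler <- V - E + Fc
  ok <- closed && euler == 2L
  if (!ok && stop_on_fail)
    stop(sprintf(
      "topology error: mesh is %s with Euler characteristic %d (need closed, 2)",
      if (closed) "closed" else "not closed", euler))
  invisible(list(closed = closed, euler = euler, genus0 = ok))
}

#' Unit icosphere mesh
#'
#' Icosahedron subdivided `level` times, vertices normalized to the unit
#' sphere. Level 0 has 12 vertices; level n has `10 * 4^n + 2`.
#'
#' @param level Subdivision level (>= 0).
#' @return An `otl_mesh` with outward-oriented faces.
#' @export
icosphere <- function(level = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (it in seq_len(level)) {
    nv <- nrow(v)
    ekey <- new.env(hash = TRUE, parent = emptyenv())
    verts <- v
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- ekey[[key]]
      if (!is.null(id)) return(id)
      p <- (verts[i, ] + verts[j, ]) / 2
      p <- p / sqrt(sum(p^2))
      verts <<- rbind(verts, p)
      id <- nrow(verts)
      ekey[[key]] <- id
      id
    }
    nf <- matrix(0L, 0, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- verts; f <- nf
  }
  # orient all faces outward (unit sphere: normal should point along centroid)
  for (t in seq_len(nrow(f))) {
    tri <- v[f[t, ], ]
    nrm <- crossprod_3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    if (sum(nrm * colMeans(tri)) < 0) f[t, ] <- f[t, c(1, 3, 2)]
  }
  otl_mesh(v, f)
}

crossprod_3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume by the divergence theorem (positive for outward-oriented
#' closed surfaces).
#'
#' @param mesh An `otl_mesh`.
#' @return Scalar volume (mm^3).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
              b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
              b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  sum(rowSums(a * cr)) / 6
}

#' Taubin smoothing
#'
#' Alternating lambda/mu uniform-weight Laplacian steps (the low-pass,
#' shrinkage-compensating scheme). Face topology is unchanged.
#'
#' @param mesh An `otl_mesh`.
#' @param lam Positive smoothing step (default 0.5).
#' @param mu Negative inflation step (default -0.53).
#' @param steps Number of lambda+mu step pairs (default 10).
#' @return Smoothed `otl_mesh`.
#' @export
taubin_smooth <- function(mesh, lam = 0.5, mu = -0.53, steps = 10L) {
  if (abs(lam) >= 1) warning("|lambda| >= 1 is outside the stable range")
  if (mu >= 0) warning("mu >= 0 disables shrinkage compensation")
  n <- nrow(mesh$vertices)
  e <- .mesh_edges(mesh)
  e <- unique(e)
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  V <- mesh$vertices
  lap <- function(V) as.matrix(A %*% V) / deg - V
  for (s in seq_len(steps)) {
    V <- V + lam * lap(V)
    V <- V + mu * lap(V)
  }
  otl_mesh(V, mesh$faces)
}

# ---------------------------------------------------------------------------
# OBJ / PLY (ascii) I/O
# ---------------------------------------------------------------------------

#' Read a triangle mesh from OBJ or ASCII PLY
#'
#' @param path File path; format inferred from the extension unless given.
#' @param format `"obj"` or `"ply"`.
#' @return An `otl_mesh`.
#' @export
read_mesh <- function(path, format = c("auto", "obj", "ply")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- tolower(tools::file_ext(path))
  if (!format %in% c("obj", "ply")) stop("unsupported mesh format: ", format)
  lines <- readLines(path)
  if (format == "obj") {
    vs <- lines[startsWith(lines, "v ")]
    fs <- lines[startsWith(lines, "f ")]
    v <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vs)), "\\s+"),
                               function(p) as.numeric(p[1:3])))
    f <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fs)), "\\s+"),
                               function(p) as.integer(sub("/.*", "", p[1:3]))))
    return(otl_mesh(v, f))
  }
  # ascii ply
  hend <- which(trimws(lines) == "end_header")[1]
  if (is.na(hend)) stop("malformed PLY: no end_header")
  header <- lines[1:hend]
  nv <- as.integer(sub(".*vertex\\s+", "", grep("element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub(".*face\\s+", "", grep("element face", header, value = TRUE)[1]))
  vlines <- lines[(hend + 1):(hend + nv)]
  flines <- lines[(hend + nv + 1):(hend + nv + nf)]
  v <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                             function(p) as.numeric(p[1:3])))
  f <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"),
                             function(p) as.integer(p[2:4]) + 1L))
  otl_mesh(v, f)
}

#' Write a triangle mesh to OBJ or ASCII PLY
#'
#' PLY output can carry one per-vertex scalar (`quality` channel), e.g. a
#' distance heatmap.
#'
#' @param mesh An `otl_mesh`.
#' @param path Output file path.
#' @param format `"obj"` or `"ply"` (inferred from extension by default).
#' @param quality Optional per-vertex scalar written as a PLY `quality`
#'   property.
#' @param digits Coordinate digits (default 9).
#' @return Invisibly, `path`.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "obj", "ply"),
                       quality = NULL, digits = 9L) {
  format <- match.arg(format)
  if (format == "auto") format <- tolower(tools::file_ext(path))
  fmt <- function(x) formatC(x, digits = digits, format = "g")
  v <- mesh$vertices; f <- mesh$faces
  if (format == "obj") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("v %s %s %s", fmt(v[, 1]), fmt(v[, 2]), fmt(v[, 3])), con)
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  } else if (format == "ply") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property float x", "property float y", "property float z",
                 if (!is.null(quality)) "property float quality",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices",
                 "end_header"), con)
    if (is.null(quality)) {
      writeLines(sprintf("%s %s %s", fmt(v[, 1]), fmt(v[, 2]), fmt(v[, 3])), con)
    } else {
      writeLines(sprintf("%s %s %s %s", fmt(v[, 1]), fmt(v[, 2]), fmt(v[, 3]),
                         fmt(quality)), con)
    }
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  } else stop("unsupported mesh format: ", format)
  invisible(path)
}
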