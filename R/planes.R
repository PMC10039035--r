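# Plane fitting and maculae-orientation comparison. Orientation is
# measured in each specimen's original (unsuperimposed) frame, since the
# quantity of interest is the attitude of the maculae relative to the
# surrounding bone.

#' Plane through a landmark triad
#'
#' @param p1,p2,p3 Non-collinear 3D points.
#' @return A `plane_fit` list: `point` (centroid), `normal` (unit vector),
#'   `rms_residual` (0 for a triad), `source = "triad"`.
#' @export
plane_from_triad <- function(p1, p2, p3) {
  P <- rbind(as.numeric(p1), as.numeric(p2), as.numeric(p3))
  e1 <- P[2, ] - P[1, ]; e2 <- P[3, ] - P[1, ]
  n <- crossprod_3(e1, e2)
  nn <- sqrt(sum(n^2))
  coll <- nn / max(sqrt(sum(e1^2)) * sqrt(sum(e2^2)), 1e-300)
  if (coll < 1e-10)
    stop(sprintf("collinear triad (sine of spanned angle = %.3g)", coll))
  structure(list(point = colMeans(P), normal = n / nn, rms_residual = 0,
                 source = "triad"), class = "plane_fit")
}

#' Total-least-squares plane through a point cloud
#'
#' Smallest principal direction of the centered points.
#'
#' @param points m x 3 matrix (m >= 3, rank >= 2).
#' @return A `plane_fit` with `source = "surface"` and the RMS
#'   point-to-plane residual.
#' @export
plane_from_surface <- function(points) {
  X <- as.matrix(points)
  if (nrow(X) < 3L) stop("need at least 3 points")
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  if (sv$d[2] < max(sv$d) * 1e-10)
    stop("rank-deficient point cloud: no unique plane")
  n <- sv$v[, 3]
  res <- Xc %*% n
  structure(list(point = colMeans(X), normal = as.numeric(n),
                 rms_residual = sqrt(mean(res^2)), source = "surface"),
            class = "plane_fit")
}

#' @export
print.plane_fit <- function(x, ...) {
  cat(sprintf("plane_fit (%s): normal (%.3f, %.3f, %.3f), rms %.4g mm\n",
              x$source, x$normal[1], x$normal[2], x$normal[3],
              x$rms_residual))
  invisible(x)
}

#' Angle between two planes
#'
#' Folded to \\[0, 90\\] degrees via the absolute dot product of the unit
#' normals, so the result does not depend on normal sign or argument
#' order.
#'
#' @param a,b `plane_fit` objects (or unit normal vectors).
#' @return Angle in degrees.
#' @export
angle_between_planes <- function(a, b) {
  na <- if (inherits(a, "plane_fit")) a$normal else as.numeric(a)
  nb <- if (inherits(b, "plane_fit")) b$normal else as.numeric(b)
  na <- na / sqrt(sum(na^2)); nb <- nb / sqrt(sum(nb^2))
  acos(min(1, abs(sum(na * nb)))) * 180 / pi
}

#' Default bony-vs-macular plane pairings
#'
#' The eight comparisons of bony-derived planes against macular planes:
#' utricular triads \{2,4,5\} and \{2,4,6\} against the utricular macula
#' (landmark triad 17-19 or macular surface), and saccular triads \{8-10\}
#' and the spherical-recess surface selection against the saccular macula
#' (landmark triad 20-22 or macular surface).
#'
#' @return Data frame with columns `name`, `bony`, `macular`; triads are
#'   comma-joined label strings, `surface:utricle` / `surface:saccule` /
#'   `surface:spherical_recess` denote point-cloud planes.
#' @export
default_plane_comparisons <- function() {
  data.frame(
    name = c("u_245_triad", "u_245_surface", "u_246_triad", "u_246_surface",
             "s_8910_triad", "s_8910_surface", "s_recess_triad",
             "s_recess_surface"),
    bony = c("LM2,LM4,LM5", "LM2,LM4,LM5", "LM2,LM4,LM6", "LM2,LM4,LM6",
             "LM8,LM9,LM10", "LM8,LM9,LM10", "surface:spherical_recess",
             "surface:spherical_recess"),
    macular = c("LM17,LM18,LM19", "surface:utricle", "LM17,LM18,LM19",
                "surface:utricle", "LM20,LM21,LM22", "surface:saccule",
                "LM20,LM21,LM22", "surface:saccule"),
    stringsAsFactors = FALSE)
}

.resolve_plane <- function(spec, config, surfaces) {
  if (startsWith(spec, "surface:")) {
    key <- sub("^surface:", "", spec)
    pts <- surfaces[[key]]
    if (is.null(pts)) stop("missing surface point set: ", key)
    plane_from_surface(pts)
  } else {
    labs <- trimws(strsplit(spec, ",")[[1]])
    idx <- match(labs, config$labels)
    if (anyNA(idx)) stop("missing label(s): ",
                         paste(labs[is.na(idx)], collapse = ", "))
    plane_from_triad(config$points[idx[1], ], config$points[idx[2], ],
                     config$points[idx[3], ])
  }
}

#' Maculae orientation analysis
#'
#' For each specimen and each bony-vs-macular pairing, computes the
#' approximation angle between the bony-derived plane and the macular
#' plane, summarizes each pairing (mean, sd, range), and regresses the
#' bony inter-plane angle (triads \{2,4,6\} vs \{8,9,10\}) on the
#' inter-macular angle (triads \{17-19\} vs \{20-22\}) across specimens.
#'
#' @param specimens List of `landmark_config` objects in their original
#'   (unsuperimposed) frames.
#' @param comparisons Pairing table as in [default_plane_comparisons()].
#' @param surfaces Optional per-specimen named list of surface point sets
#'   (`surfaces[[specimen]][[key]]`); pairings needing a missing surface
#'   are skipped for that specimen.
#' @return List with `angles` (long data frame), `summary` (per pairing),
#'   and `interplane_regression` (an `ols_fit` of bony angle on macular
#'   angle, plus the per-specimen angle table).
#' @export
maculae_orientation_analysis <- function(specimens,
                                         comparisons = default_plane_comparisons(),
                                         surfaces = NULL) {
  rows <- list()
  for (cfg in specimens) {
    sid <- cfg$specimen_id
    surf <- if (!is.null(surfaces)) surfaces[[sid]] else NULL
    for (i in seq_len(nrow(comparisons))) {
      cmp <- comparisons[i, ]
      ang <- tryCatch({
        pb <- .resolve_plane(cmp$bony, cfg, surf)
        pm <- .resolve_plane(cmp$macular, cfg, surf)
        angle_between_planes(pb, pm)
      }, error = function(e) NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        specimen_id = sid, name = cmp$name, bony = cmp$bony,
        macular = cmp$macular, angle_deg = ang, stringsAsFactors = FALSE)
    }
  }
  angles <- do.call(rbind, rows)
  ok <- !is.na(angles$angle_deg)
  summ <- do.call(rbind, lapply(split(angles[ok, ], angles$name[ok]), function(d)
    data.frame(name = d$name[1], n = nrow(d), mean_deg = mean(d$angle_deg),
               sd_deg = sd(d$angle_deg), min_deg = min(d$angle_deg),
               max_deg = max(d$angle_deg), stringsAsFactors = FALSE)))
  rownames(summ) <- NULL

  inter <- do.call(rbind, lapply(specimens, function(cfg) {
    a <- tryCatch({
      b1 <- .resolve_plane("LM2,LM4,LM6", cfg, NULL)
      b2 <- .resolve_plane("LM8,LM9,LM10", cfg, NULL)
      m1 <- .resolve_plane("LM17,LM18,LM19", cfg, NULL)
      m2 <- .resolve_plane("LM20,LM21,LM22", cfg, NULL)
      c(bony = angle_between_planes(b1, b2),
        macular = angle_between_planes(m1, m2))
    }, error = function(e) c(bony = NA_real_, macular = NA_real_))
    data.frame(specimen_id = cfg$specimen_id, bony_angle = a["bony"],
               macular_angle = a["macular"], stringsAsFactors = FALSE)
  }))
  rownames(inter) <- NULL
  reg <- tryCatch(
    ols_regress(inter$macular_angle[!is.na(inter$macular_angle)],
                inter$bony_angle[!is.na(inter$bony_angle)]),
    error = function(e) NULL)
  list(angles = angles, summary = summ,
       interplane_regression = list(fit = reg, table = inter))
}
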