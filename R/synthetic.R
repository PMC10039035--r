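# Synthetic labyrinth generator: specimen populations (landmark
# configurations + genus-0 mesh trios) with known ground truth for every
# pipeline stage — controlled bone-membrane covariation, modular or
# integrated covariance structure, known bony-vs-macular plane offsets.

# base geometry (mm): ellipsoid centers and semi-axes
.syn_geom <- function() {
  list(
    vestibule = list(center = c(0, 0, 0),        axes = c(2.0, 1.7, 1.5)),
    utricle   = list(center = c(0, 0.35, 0.55),  axes = c(1.05, 0.55, 0.28)),
    saccule   = list(center = c(-0.45, -0.35, -0.45), axes = c(0.6, 0.5, 0.42))
  )
}

.unit <- function(v) v / sqrt(sum(v^2))

# fixed landmark directions on each structure's parameter sphere
.syn_directions <- function() {
  bony <- rbind(
    LM1  = c(0.95, 0.05, 0.30),
    LM2  = c(0.70, 0.50, 0.50),
    LM3  = c(-0.10, 0.95, 0.30),
    LM4  = c(-0.50, 0.55, 0.67),
    LM5  = c(-0.95, 0.10, -0.30),
    LM6  = c(0.20, -0.60, 0.78),
    LM7  = c(0.60, -0.75, -0.28),
    LM8  = c(-0.85, -0.30, -0.43),
    LM9  = c(-0.30, -0.85, -0.43),
    LM10 = c(-0.45, -0.20, -0.87))
  utric <- rbind(
    LM11 = c(0.90, 0.30, 0.30),
    LM12 = c(-0.90, 0.20, 0.35),
    LM13 = c(0.00, -0.90, 0.44))
  sacc <- rbind(
    LM14 = c(0.85, 0.35, 0.40),
    LM15 = c(-0.30, 0.90, 0.30),
    LM16 = c(-0.60, -0.55, 0.58))
  list(bony = t(apply(bony, 1, .unit)),
       utricle = t(apply(utric, 1, .unit)),
       saccule = t(apply(sacc, 1, .unit)))
}

# open-ring curve directions: angular-radius ring around an axis
.ring_directions <- function(axis, angular_radius_deg, n, span_deg = 300) {
  axis <- .unit(axis)
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- .unit(crossprod_3(axis, ref))
  e2 <- crossprod_3(axis, e1)
  th <- angular_radius_deg * pi / 180
  phi <- seq(0, span_deg * pi / 180, length.out = n)
  t(vapply(phi, function(p)
    cos(th) * axis + sin(th) * (cos(p) * e1 + sin(p) * e2), numeric(3)))
}

.syn_curve_directions <- function() {
  list(
    SemiLM1 = .ring_directions(c(0.15, 0.10, 0.98), 62, 20),  # vestibule girdle
    SemiLM2 = .ring_directions(c(0.75, -0.60, -0.10), 24, 18),# oval window rim
    SemiLM3 = .ring_directions(c(0, 0, 1), 88, 16)            # utricle equator
  )
}

# fixed low-degree field directions (package constants; generated once
# from a private RNG stream so user seeds never change the "anatomy")
.syn_field_constants <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    })
    set.seed(902131L)
    rnd <- function() .unit(rnorm(12))
    cache <<- list(w_vest = rnd(), w_utr = rnd(), w_sac = rnd(),
                   w_vest2 = rnd())
    cache
  }
})

# radial spherical-harmonic modulation field: degrees 2-3 (12 basis
# functions), optionally weighted by a degree-1 hemispheric factor
.syn_field <- function(u, coefs, hemi = 0) {
  g <- as.numeric(sph_basis(u, 3L)[, 5:16, drop = FALSE] %*% coefs)
  if (hemi != 0) g <- g * (1 + hemi * u[, 3]) / 2
  g
}

.syn_surface <- function(geom, u, coefs, hemi = 0) {
  g <- if (all(coefs == 0)) rep(0, nrow(u)) else .syn_field(u, coefs, hemi)
  sweep(u %*% diag(geom$axes) * (1 + g), 2, geom$center, `+`)
}

.rotation_about_axis <- function(axis, angle_deg) {
  a <- .unit(axis); th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

.plane_frame <- function(normal) {
  n <- .unit(normal)
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .unit(crossprod_3(n, ref))
  e2 <- crossprod_3(n, e1)
  list(e1 = e1, e2 = e2)
}

#' Specification of a synthetic labyrinth population
#'
#' Defaults encode the study conditions the package is designed around:
#' 12 specimens, the full 22 + 86 landmark scheme, a bone-membrane shape
#' covariation targeting R-squared 0.5 (the middle of the biologically
#' plausible 0.3-0.6 band), mean bony-vs-macular plane offsets of 4.6
#' degrees, and 0.008 mm landmark noise (an order of magnitude below the
#' deformation signal, emulating careful manual landmarking).
#'
#' @param n_specimens Number of specimens (default 12).
#' @param seed Integer RNG seed (Mersenne-Twister via [set.seed()]).
#' @param bone_membrane_r2 Target R-squared of the bone-to-membrane
#'   factor regression, in `[0, 1]`.
#' @param covariance_mode `"integrated"` (one shared membranous factor
#'   correlated with the bony factor), `"modular"` (independent
#'   greater-utricle and greater-saccule factors) or `"null"` (no factor
#'   structure; isotropic landmark noise only).
#' @param plane_offset_deg Mean bony-vs-macular plane offset (degrees).
#' @param plane_offset_sd_deg Between-specimen sd of the offset.
#' @param landmark_noise_sd Isotropic landmark noise sd (mm).
#' @param mesh_subdivision Icosphere subdivision level of generated
#'   meshes.
#' @param meshes Generate mesh trios (default `TRUE`; landmark-only
#'   populations are faster for statistical calibration).
#' @param angle_r2 Optional target R-squared of the inter-plane angle
#'   correlation (bony vs macular); `NULL` keeps independent offsets.
#' @param deformation_amplitude Factor amplitude of the radial shape
#'   fields (fractional, default 0.05).
#' @param jitter_sd Optional idiosyncratic shape jitter (default 0: the
#'   covariance structure is exactly the one the mode declares, plus
#'   landmark noise). In integrated mode a positive value is the sd of a
#'   per-specimen global strain (symmetric traceless linear map of the
#'   whole labyrinth) — variation common to every landmark at full
#'   strength, hence non-modular. In modular mode it is the
#'   per-coefficient sd of small per-structure smooth fields.
#' @return A `population_spec` list.
#' @export
population_spec <- function(n_specimens = 12L, seed = 1L,
                            bone_membrane_r2 = 0.5,
                            covariance_mode = c("integrated", "modular", "null"),
                            plane_offset_deg = 4.6,
                            plane_offset_sd_deg = 1.9,
                            landmark_noise_sd = 0.008,
                            mesh_subdivision = 3L,
                            meshes = TRUE,
                            angle_r2 = NULL,
                            deformation_amplitude = 0.05,
                            jitter_sd = 0) {
  covariance_mode <- match.arg(covariance_mode)
  if (bone_membrane_r2 < 0 || bone_membrane_r2 > 1)
    stop("infeasible bone_membrane_r2: the factor variance budget requires ",
         "a value in [0, 1]")
  if (!is.null(angle_r2) && (angle_r2 < 0 || angle_r2 > 1))
    stop("angle_r2 must be in [0, 1]")
  structure(list(n_specimens = as.integer(n_specimens), seed = as.integer(seed),
                 bone_membrane_r2 = bone_membrane_r2,
                 covariance_mode = covariance_mode,
                 plane_offset_deg = plane_offset_deg,
                 plane_offset_sd_deg = plane_offset_sd_deg,
                 landmark_noise_sd = landmark_noise_sd,
                 mesh_subdivision = as.integer(mesh_subdivision),
                 meshes = meshes, angle_r2 = angle_r2,
                 deformation_amplitude = deformation_amplitude,
                 jitter_sd = jitter_sd),
            class = "population_spec")
}

#' Base (undeformed) landmark positions of the synthetic labyrinth
#'
#' @return 108 x 3 matrix in scheme order with labels as rownames; macular
#'   points are at their zero-offset positions.
#' @export
synthetic_base_landmarks <- function() {
  g <- generate_population(population_spec(
    n_specimens = 2L, seed = 1L, covariance_mode = "null",
    landmark_noise_sd = 0, plane_offset_deg = 0, plane_offset_sd_deg = 0,
    meshes = FALSE))
  g[[1]]$config$points
}

#' Bony fiducial positions for a synthetic structure mesh
#'
#' Base-shape surface points at the landmark directions of the given
#' structure, usable as fiducials on mean meshes.
#'
#' @param structure `"vestibule"`, `"utricle"` or `"saccule"`.
#' @return k x 3 matrix with landmark labels as rownames.
#' @export
synthetic_fiducials <- function(structure = c("vestibule", "utricle", "saccule")) {
  structure <- match.arg(structure)
  geom <- .syn_geom()[[structure]]
  dirs <- switch(structure,
                 vestibule = .syn_directions()$bony,
                 utricle = .syn_directions()$utricle,
                 saccule = .syn_directions()$saccule)
  pts <- .syn_surface(geom, dirs, rep(0, 12))
  rownames(pts) <- rownames(dirs)
  pts
}

#' Generate a synthetic specimen population
#'
#' Produces `n_specimens` labyrinths: a full 108-point landmark
#' configuration, an optional genus-0 mesh trio (vestibule, utricle,
#' saccule), and a ground-truth record of every generating parameter.
#' Per-specimen shape deviations are smooth low-degree spherical-harmonic
#' radial fields whose bony and membranous factor scores achieve the
#' requested bone-membrane R-squared; maculae landmark triads and
#' contours lie on planes offset from the (base) bony triad planes by
#' `plane_offset_deg` plus noise.
#'
#' @param spec A `population_spec`.
#' @return List of specimens, each a list with `config`
#'   (`landmark_config`), `meshes` (named list of `otl_mesh` or `NULL`)
#'   and `truth`; the population-level ground truth (factor scores,
#'   offsets, parameters) is attached as `attr(, "truth")`.
#' @export
generate_population <- function(spec = population_spec()) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  geom <- .syn_geom()
  dirs <- .syn_directions()
  curves <- .syn_curve_directions()
  const <- .syn_field_constants()
  scheme <- otolith_scheme()
  n <- spec$n_specimens
  r2 <- spec$bone_membrane_r2
  amp <- spec$deformation_amplitude
  jit <- spec$jitter_sd

  # factor scores
  f <- rnorm(n)                       # bony factor
  g_ind <- rnorm(n)
  m <- sqrt(r2) * f + sqrt(1 - r2) * g_ind   # membranous factor
  f2 <- rnorm(n)                      # second factor (modular mode)

  # plane offsets: every latent source follows the covariance mode.
  # Integrated populations drive the macular tilts with the shared
  # membranous factor; modular populations tie each macula to its module
  # factor; the null mode carries no per-specimen structure of any kind
  # (offsets frozen at their mean), so landmark noise is the only source
  # of variation and landmarks are exchangeable.
  if (spec$covariance_mode == "null") {
    du <- rep(spec$plane_offset_deg, n)
    ds <- rep(spec$plane_offset_deg, n)
  } else if (spec$covariance_mode == "modular") {
    du <- spec$plane_offset_deg + spec$plane_offset_sd_deg * f
    ds <- spec$plane_offset_deg + spec$plane_offset_sd_deg * f2
  } else {
    du <- spec$plane_offset_deg + spec$plane_offset_sd_deg * m
    ds <- spec$plane_offset_deg + spec$plane_offset_sd_deg * m
  }

  # optional correlated inter-plane angle construction
  use_angle <- !is.null(spec$angle_r2)
  if (use_angle) {
    z_a <- rnorm(n); w_a <- rnorm(n)
    s_a <- 3   # degrees of angle modulation
    alpha <- s_a * z_a                               # bony triad rotation
    m_ang <- s_a * (sqrt(spec$angle_r2) * z_a + sqrt(1 - spec$angle_r2) * w_a)
  }

  # base bony triad planes (undeformed); fixed in-plane tilt axes come from
  # the base planes so the tilt direction is anatomically consistent
  base_bony <- .syn_surface(geom$vestibule, dirs$bony, rep(0, 12))
  rownames(base_bony) <- rownames(dirs$bony)
  pl_u <- plane_from_triad(base_bony["LM2", ], base_bony["LM4", ],
                           base_bony["LM6", ])
  pl_s <- plane_from_triad(base_bony["LM8", ], base_bony["LM9", ],
                           base_bony["LM10", ])
  ax_u <- .plane_frame(pl_u$normal)$e1
  ax_s <- .plane_frame(pl_s$normal)$e1
  p_u <- geom$utricle$center + c(0.10, 0.15, -0.22)   # utricular macula center
  p_s <- geom$saccule$center + c(-0.15, -0.10, -0.10) # saccular macula center

  ico <- if (spec$meshes) icosphere(spec$mesh_subdivision) else NULL

  null_mode <- spec$covariance_mode == "null"
  modular <- spec$covariance_mode == "modular"

  out <- vector("list", n)
  for (i in seq_len(n)) {
    # per-structure radial field coefficients
    if (null_mode) {
      cv <- cu <- cs <- rep(0, 12)
      hemi_extra <- NULL
    } else if (modular) {
      cu <- amp * f[i] * const$w_utr + jit * rnorm(12)
      cs <- amp * f2[i] * const$w_sac + jit * rnorm(12)
      # bony field: utricle factor weighted to the upper hemisphere,
      # saccule factor to the lower (degree-1 modulation keeps it a
      # low-degree spherical-harmonic field)
      cv <- jit * rnorm(12)
      hemi_extra <- list(list(coefs = amp * f[i] * const$w_vest, hemi = +1),
                         list(coefs = amp * f2[i] * const$w_vest2, hemi = -1))
    } else {
      cv <- amp * f[i] * const$w_vest
      cu <- amp * m[i] * const$w_utr
      cs <- amp * m[i] * const$w_sac
      hemi_extra <- NULL
    }
    # integrated-mode jitter: a global strain (random symmetric traceless
    # linear map) of the whole labyrinth — variation that is common to
    # every landmark at full strength, hence non-modular; rotation and
    # isotropic size changes would be absorbed by superimposition anyway
    strain <- NULL
    if (!null_mode && !modular && jit > 0) {
      Em <- matrix(rnorm(9, 0, jit), 3, 3)
      Em <- (Em + t(Em)) / 2
      Em <- Em - diag(3) * sum(diag(Em)) / 3
      strain <- diag(3) + Em
    }

    vest_surface <- function(u) {
      p <- .syn_surface(geom$vestibule, u, cv)
      if (!is.null(hemi_extra)) {
        base <- u %*% diag(geom$vestibule$axes)
        for (hx in hemi_extra) {
          gmod <- .syn_field(u, hx$coefs, hemi = hx$hemi)
          p <- p + base * gmod
        }
      }
      p
    }

    # bony single landmarks + curves
    bony_pts <- vest_surface(dirs$bony)
    rownames(bony_pts) <- rownames(dirs$bony)
    if (use_angle) {
      # rotate the spherical-recess triad about its centroid
      tri <- bony_pts[c("LM8", "LM9", "LM10"), ]
      ctr <- colMeans(tri)
      R <- .rotation_about_axis(ax_s, alpha[i])
      bony_pts[c("LM8", "LM9", "LM10"), ] <-
        sweep(sweep(tri, 2, ctr) %*% t(R), 2, ctr, `+`)
    }
    semi1 <- vest_surface(curves$SemiLM1)
    semi2 <- vest_surface(curves$SemiLM2)

    # membranous organs
    utr_pts <- .syn_surface(geom$utricle, dirs$utricle, cu)
    rownames(utr_pts) <- rownames(dirs$utricle)
    sac_pts <- .syn_surface(geom$saccule, dirs$saccule, cs)
    rownames(sac_pts) <- rownames(dirs$saccule)
    semi3 <- .syn_surface(geom$utricle, curves$SemiLM3, cu)

    # maculae: planes offset from the BASE bony triad planes. Placing them
    # relative to the specimen's deformed planes would make the offsets
    # exact, but it deterministically couples macular orientation to the
    # bony factor and inflates the delivered bone-membrane R2 beyond the
    # requested target; base-plane placement keeps the covariance budget
    # exactly as declared, at the cost of a small positive bias in
    # recovered offsets (the deformation tilt of the measured bony plane
    # folds into the angle).
    n_u <- as.numeric(.rotation_about_axis(ax_u, du[i]) %*% pl_u$normal)
    fr_u <- .plane_frame(n_u)
    tri_ang <- c(90, 210, 330) * pi / 180
    mac_u <- t(vapply(tri_ang, function(a)
      p_u + 0.45 * (cos(a) * fr_u$e1 + sin(a) * fr_u$e2), numeric(3)))
    rownames(mac_u) <- paste0("LM", 17:19)
    phi4 <- seq(0, 2 * pi * 15 / 16, length.out = 16)
    semi4 <- t(vapply(phi4, function(a)
      p_u + 0.55 * cos(a) * fr_u$e1 + 0.35 * sin(a) * fr_u$e2, numeric(3)))

    if (use_angle) {
      n_s <- as.numeric(.rotation_about_axis(.plane_frame(n_u)$e1, m_ang[i] +
                                               spec$plane_offset_deg) %*% n_u)
    } else {
      n_s <- as.numeric(.rotation_about_axis(ax_s, ds[i]) %*% pl_s$normal)
    }
    fr_s <- .plane_frame(n_s)
    mac_s <- t(vapply(tri_ang, function(a)
      p_s + 0.30 * (cos(a) * fr_s$e1 + sin(a) * fr_s$e2), numeric(3)))
    rownames(mac_s) <- paste0("LM", 20:22)
    semi5 <- t(vapply(phi4, function(a)
      p_s + 0.38 * cos(a) * fr_s$e1 + 0.28 * sin(a) * fr_s$e2, numeric(3)))

    pts <- rbind(bony_pts,
                 utr_pts, sac_pts, mac_u, mac_s,
                 semi1, semi2, semi3, semi4, semi5)
    # scheme order: LM1-10, LM11-16, LM17-22, SemiLM1..5
    rownames(pts) <- NULL
    pts <- pts[c(1:10, 11:13, 14:16, 17:19, 20:22,
                 22 + seq_len(sum(.semilm_counts))), , drop = FALSE]
    if (!is.null(strain)) pts <- pts %*% t(strain)
    if (spec$landmark_noise_sd > 0)
      pts <- pts + matrix(rnorm(length(pts), 0, spec$landmark_noise_sd),
                          nrow(pts), 3)
    cfg <- landmark_config(pts, labels = scheme$label,
                           specimen_id = sprintf("syn%02d", i))

    meshes <- NULL
    if (spec$meshes) {
      sv <- function(P) if (is.null(strain)) P else P %*% t(strain)
      mv <- otl_mesh(sv(vest_surface(ico$vertices)), ico$faces)
      mu <- otl_mesh(sv(.syn_surface(geom$utricle, ico$vertices, cu)),
                     ico$faces)
      ms <- otl_mesh(sv(.syn_surface(geom$saccule, ico$vertices, cs)),
                     ico$faces)
      meshes <- list(vestibule = mv, utricle = mu, saccule = ms)
    }
    out[[i]] <- list(config = cfg, meshes = meshes,
                     truth = list(f = f[i], m = m[i], f2 = f2[i],
                                  delta_u = du[i], delta_s = ds[i],
                                  coefs = list(vestibule = cv, utricle = cu,
                                               saccule = cs)))
  }
  attr(out, "truth") <- list(spec = spec, f = f, m = m, f2 = f2,
                             delta_u = du, delta_s = ds,
                             angle = if (use_angle)
                               list(alpha = alpha, m_ang = m_ang) else NULL)
  out
}

#' Generate a modular-covariance population
#'
#' Convenience wrapper: two independent within-module factors
#' (greater-utricle and greater-saccule) plus small shared jitter; true
#' module labels follow the set-6 split.
#'
#' @param spec A `population_spec`; its `covariance_mode` is forced to
#'   `"modular"`.
#' @return As [generate_population()], with `attr(, "module_labels")`
#'   giving the true greater-utricle / greater-saccule assignment.
#' @export
generate_modular_population <- function(spec = population_spec()) {
  spec$covariance_mode <- "modular"
  out <- generate_population(spec)
  attr(out, "module_labels") <- landmark_set(6)$blocks
  out
}

#' Write a small deterministic fixture tree
#'
#' Three coarse specimens in every supported format (.fcsv, landmark CSV,
#' OBJ, PLY). Deterministic for a given seed: re-running produces
#' byte-identical files.
#'
#' @param outdir Output directory (created).
#' @param seed Seed (default 1).
#' @return Invisibly, the written file paths.
#' @export
write_fixture_suite <- function(outdir, seed = 1L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pop <- generate_population(population_spec(
    n_specimens = 3L, seed = seed, mesh_subdivision = 2L))
  paths <- character(0)
  for (i in seq_along(pop)) {
    cfg <- pop[[i]]$config
    id <- cfg$specimen_id
    p1 <- file.path(outdir, paste0(id, ".fcsv"))
    write_fcsv(cfg, p1)
    p2 <- file.path(outdir, paste0(id, ".csv"))
    write_landmark_csv(cfg, p2)
    p3 <- file.path(outdir, paste0(id, "_utricle.obj"))
    write_mesh(pop[[i]]$meshes$utricle, p3)
    p4 <- file.path(outdir, paste0(id, "_saccule.ply"))
    write_mesh(pop[[i]]$meshes$saccule, p4)
    paths <- c(paths, p1, p2, p3, p4)
  }
  invisible(paths)
}
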