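#' @useDynLib otolithmorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef cor dist lm median prcomp quantile rnorm runif sd var wilcox.test pf setNames
#' @importFrom utils read.csv write.csv head tail
"_PACKAGE"

# ---------------------------------------------------------------------------
# Landmark scheme: 22 single landmarks (LM1-LM22) and 5 semilandmark curves
# totalling 86 points. LM1-10 lie on the bony vestibule wall, LM11-22 on the
# membranous organs (LM17-19 utricular macula triad, LM20-22 saccular macula
# triad). SemiLM1-2 are bony curves (SemiLM2 rings the oval window), SemiLM3-5
# are membranous curves (SemiLM4 utricular macula contour, SemiLM5 saccular
# macula contour).
# ---------------------------------------------------------------------------

.semilm_counts <- c(SemiLM1 = 20L, SemiLM2 = 18L, SemiLM3 = 16L,
                    SemiLM4 = 16L, SemiLM5 = 16L)

#' Full otolith-system landmark scheme
#'
#' Returns the canonical 108-point scheme: 22 single landmarks plus 86
#' semilandmarks on five curves, with tissue-block assignments. Point order
#' in this table is the homology contract used throughout the package:
#' index i always refers to the same anatomical point.
#'
#' @return A data frame with columns `label`, `role` (`"single"` or
#'   `"semi"`), `curve` (`NA` or `"SemiLM1"`..`"SemiLM5"`) and `block`
#'   (`"bony"` or `"membranous"`).
#' @export
otolith_scheme <- function() {
  singles <- data.frame(
    label = paste0("LM", 1:22),
    role  = "single",
    curve = NA_character_,
    block = c(rep("bony", 10), rep("membranous", 12)),
    stringsAsFactors = FALSE
  )
  semis <- do.call(rbind, lapply(names(.semilm_counts), function(cv) {
    n <- .semilm_counts[[cv]]
    data.frame(
      label = sprintf("%s_%02d", cv, seq_len(n)),
      role  = "semi",
      curve = cv,
      block = if (cv %in% c("SemiLM1", "SemiLM2")) "bony" else "membranous",
      stringsAsFactors = FALSE
    )
  }))
  rbind(singles, semis)
}

#' Construct a landmark configuration
#'
#' A `landmark_config` holds one specimen's named 3D points (mm) together
#' with their single-vs-semilandmark role, curve membership and tissue
#' block.
#'
#' @param points Numeric k x 3 matrix of coordinates (mm).
#' @param labels Character vector of per-point anatomical labels.
#' @param role Per-point role, `"single"` or `"semi"`. Defaults to the
#'   canonical scheme when `labels` follow it.
#' @param curve Per-point curve id (`NA` for single landmarks).
#' @param block Per-point tissue block, `"bony"` or `"membranous"`.
#' @param specimen_id Specimen identifier.
#' @return An object of class `landmark_config`.
#' @export
landmark_config <- function(points, labels = NULL, role = NULL, curve = NULL,
                            block = NULL, specimen_id = "specimen") {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L)
    stop("`points` must be a k x 3 matrix")
  k <- nrow(points)
  if (k < 3L) stop("invalid configuration: need at least 3 points")
  if (!all(is.finite(points)))
    stop("invalid configuration: non-finite coordinates")
  if (is.null(labels)) labels <- rownames(points)
  if (is.null(labels)) labels <- sprintf("P%03d", seq_len(k))
  labels <- as.character(labels)
  if (length(labels) != k) stop("labels length must match point count")

  scheme <- otolith_scheme()
  m <- match(labels, scheme$label)
  if (is.null(role))  role  <- ifelse(!is.na(m), scheme$role[m], "single")
  if (is.null(curve)) curve <- ifelse(!is.na(m), scheme$curve[m], NA_character_)
  if (is.null(block)) block <- ifelse(!is.na(m), scheme$block[m], NA_character_)
  role <- rep_len(as.character(role), k)
  curve <- rep_len(as.character(curve), k)
  block <- rep_len(as.character(block), k)

  single <- role == "single"
  if (anyDuplicated(labels[single]))
    stop("labels must be unique among single landmarks")
  if (any(role == "semi" & is.na(curve)))
    stop("every semilandmark needs a curve id")
  # curve point order must be contiguous in the configuration
  for (cv in unique(curve[!is.na(curve)])) {
    idx <- which(curve == cv & role == "semi")
    if (length(idx) && !all(diff(idx) == 1L))
      stop(sprintf("semilandmarks of %s are not contiguous", cv))
  }
  rownames(points) <- labels
  structure(list(specimen_id = specimen_id, points = points, labels = labels,
                 role = role, curve = curve, block = block),
            class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat(sprintf("landmark_config '%s': %d points (%d single, %d semilandmarks)\n",
              x$specimen_id, nrow(x$points), sum(x$role == "single"),
              sum(x$role == "semi")))
  cat(sprintf("  blocks: %s\n",
              paste(sprintf("%s=%d", names(table(x$block)), table(x$block)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
as.matrix.landmark_config <- function(x, ...) x$points

.config_points <- function(x) {
  if (inherits(x, "landmark_config")) x$points else {
    m <- as.matrix(x); storage.mode(m) <- "double"; m
  }
}

#' Centroid size of a configuration
#'
#' Square root of the summed squared distances of all points from their
#' centroid — the standard geometric-morphometrics size measure (mm).
#'
#' @param config A `landmark_config` or k x 3 coordinate matrix.
#' @return Positive scalar centroid size.
#' @export
centroid_size <- function(config) {
  x <- .config_points(config)
  if (nrow(x) < 2L) stop("invalid configuration: need at least 2 points")
  if (!all(is.finite(x))) stop("invalid configuration: non-finite coordinates")
  xc <- sweep(x, 2, colMeans(x))
  sqrt(sum(xc^2))
}

# ---------------------------------------------------------------------------
# Landmark set definitions (analysis sets 1-6)
# ---------------------------------------------------------------------------

#' Landmark set definitions used by the analyses
#'
#' Six nested/derived selections of the full scheme: set 1 is the complete
#' configuration; set 2 drops the oval-window curve (SemiLM2); set 3 keeps
#' single landmarks only; set 4 further drops LM5 (the most variable
#' landmark); set 5 additionally drops LM7; set 6 splits the points into
#' greater-utricle and greater-saccule modules (bony LM1-6, membranous
#' LM11-13 + LM17-19, SemiLM3-4 vs bony LM7-10, membranous LM14-16 +
#' LM20-22, SemiLM1, 2 and 5).
#'
#' @param set_id Integer 1-6.
#' @return A `landmark_set` object with fields `set_id`, `labels` (included
#'   point labels in scheme order) and `blocks` (named block per label).
#' @export
landmark_set <- function(set_id) {
  set_id <- as.integer(set_id)
  if (!set_id %in% 1:6) stop("set_id must be in 1..6")
  scheme <- otolith_scheme()
  keep <- rep(TRUE, nrow(scheme))
  if (set_id == 2L) keep <- is.na(scheme$curve) | scheme$curve != "SemiLM2"
  if (set_id >= 3L && set_id <= 5L) keep <- scheme$role == "single"
  if (set_id %in% 4:5) keep <- keep & scheme$label != "LM5"
  if (set_id == 5L) keep <- keep & scheme$label != "LM7"
  labels <- scheme$label[keep]
  blocks <- scheme$block[keep]
  if (set_id == 6L) {
    gu_singles <- c(paste0("LM", 1:6), paste0("LM", 11:13), paste0("LM", 17:19))
    gu_curves <- c("SemiLM3", "SemiLM4")
    gu <- scheme$label %in% gu_singles |
      (!is.na(scheme$curve) & scheme$curve %in% gu_curves)
    blocks <- ifelse(gu, "greater_utricle", "greater_saccule")[keep]
  }
  names(blocks) <- labels
  structure(list(set_id = set_id, labels = labels, blocks = blocks),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("landmark_set %d: %d points; blocks: %s\n", x$set_id,
              length(x$labels),
              paste(sprintf("%s=%d", names(table(x$blocks)), table(x$blocks)),
                    collapse = ", ")))
  invisible(x)
}

#' Single-landmark subsets used by the centroid-size battery
#'
#' Named subsets of the single landmarks: five bony and four membranous
#' groupings of the structures directly surrounding / composing each
#' otolith organ.
#'
#' @return Named list of character vectors of landmark labels.
#' @export
centroid_size_subsets <- function() {
  list(
    bony_utricle          = paste0("LM", 1:6),
    bony_utricle_reduced  = paste0("LM", c(1:4, 6)),
    bony_saccule          = paste0("LM", 7:10),
    spherical_recess      = paste0("LM", 8:10),
    bony_all              = paste0("LM", 1:10),
    membranous_utricle    = paste0("LM", c(11:13, 17:19)),
    utricular_macula      = paste0("LM", 17:19),
    membranous_saccule    = paste0("LM", c(14:16, 20:22)),
    saccular_macula       = paste0("LM", 20:22)
  )
}
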