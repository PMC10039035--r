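# Landmark file I/O: 3D Slicer .fcsv and .mrk.json markups, plain
# landmark CSV, and classic TPS text. Coordinates are stored in RAS, mm,
# right-handed; LPS files are sign-flipped on x and y at read time.

.fmt_num <- function(x, digits = 9L) formatC(x, digits = digits, format = "g")

#' Write landmarks as 3D Slicer .fcsv
#'
#' @param config A `landmark_config`.
#' @param path Output path.
#' @param coordinate_system `"RAS"` (default) or `"LPS"`.
#' @return Invisibly, `path`.
#' @export
write_fcsv <- function(config, path, coordinate_system = c("RAS", "LPS")) {
  coordinate_system <- match.arg(coordinate_system)
  P <- config$points
  if (coordinate_system == "LPS") P[, 1:2] <- -P[, 1:2]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# Markups fiducial file version = 4.11",
               sprintf("# CoordinateSystem = %s", coordinate_system),
               "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID"),
             con)
  k <- nrow(P)
  writeLines(sprintf("%d,%s,%s,%s,0,0,0,1,1,1,0,%s,%s,", seq_len(k),
                     .fmt_num(P[, 1]), .fmt_num(P[, 2]), .fmt_num(P[, 3]),
                     config$labels, config$specimen_id), con)
  invisible(path)
}

#' Read landmarks from a 3D Slicer .fcsv file
#'
#' Header lines start with `#`; a `CoordinateSystem` header of LPS
#' triggers conversion to RAS (sign flip on x and y).
#'
#' @param path Input path.
#' @param specimen_id Specimen id (defaults to the file stem).
#' @return A `landmark_config`.
#' @export
read_fcsv <- function(path, specimen_id = NULL) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(body)) stop("no landmark rows in ", path)
  lps <- any(grepl("CoordinateSystem\\s*=\\s*(LPS|1)", hdr))
  parts <- strsplit(body, ",")
  bad <- which(vapply(parts, length, 1L) < 12L)
  if (length(bad))
    stop("malformed .fcsv rows at line(s): ",
         paste(which(!startsWith(lines, "#"))[bad], collapse = ", "))
  P <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  labels <- vapply(parts, function(p) p[12], character(1))
  if (anyNA(P)) stop("non-numeric coordinates in ", path)
  if (lps) P[, 1:2] <- -P[, 1:2]
  if (is.null(specimen_id))
    specimen_id <- sub("\\.fcsv$", "", basename(path))
  landmark_config(P, labels, specimen_id = specimen_id)
}

#' Write landmarks as Slicer .mrk.json markups
#'
#' @inheritParams write_fcsv
#' @export
write_mrk_json <- function(config, path, coordinate_system = c("RAS", "LPS")) {
  coordinate_system <- match.arg(coordinate_system)
  P <- config$points
  if (coordinate_system == "LPS") P[, 1:2] <- -P[, 1:2]
  cps <- lapply(seq_len(nrow(P)), function(i)
    list(id = as.character(i), label = config$labels[i],
         position = as.numeric(P[i, ])))
  doc <- list(markups = list(list(type = "Fiducial",
                                  coordinateSystem = coordinate_system,
                                  controlPoints = cps)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read landmarks from Slicer .mrk.json markups
#'
#' @inheritParams read_fcsv
#' @export
read_mrk_json <- function(path, specimen_id = NULL) {
  doc <- jsonlite::read_json(path)
  mk <- doc$markups[[1]]
  cps <- mk$controlPoints
  if (is.null(cps) || !length(cps)) stop("no control points in ", path)
  P <- t(vapply(cps, function(cp) as.numeric(unlist(cp$position)), numeric(3)))
  labels <- vapply(cps, function(cp) as.character(cp$label), character(1))
  cs <- mk$coordinateSystem
  if (!is.null(cs) && toupper(cs) == "LPS") P[, 1:2] <- -P[, 1:2]
  if (is.null(specimen_id))
    specimen_id <- sub("\\.mrk\\.json$", "", basename(path))
  landmark_config(P, labels, specimen_id = specimen_id)
}

#' Write landmarks as plain CSV
#'
#' Columns: specimen, label, role, curve, block, x, y, z.
#'
#' @param config A `landmark_config`.
#' @param path Output path.
#' @export
write_landmark_csv <- function(config, path) {
  d <- data.frame(specimen = config$specimen_id, label = config$labels,
                  role = config$role, curve = config$curve,
                  block = config$block,
                  x = .fmt_num(config$points[, 1]),
                  y = .fmt_num(config$points[, 2]),
                  z = .fmt_num(config$points[, 3]),
                  stringsAsFactors = FALSE)
  write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read landmarks from plain CSV
#'
#' @inheritParams read_fcsv
#' @export
read_landmark_csv <- function(path, specimen_id = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(d)))
    stop("landmark CSV must have columns: ", paste(need, collapse = ", "))
  P <- as.matrix(d[, c("x", "y", "z")])
  storage.mode(P) <- "double"
  if (is.null(specimen_id))
    specimen_id <- if ("specimen" %in% names(d) && nrow(d)) d$specimen[1]
  else sub("\\.csv$", "", basename(path))
  cv <- if ("curve" %in% names(d)) ifelse(d$curve == "" | is.na(d$curve),
                                          NA_character_, d$curve) else NULL
  landmark_config(P, d$label,
                  role = if ("role" %in% names(d)) d$role else NULL,
                  curve = cv,
                  block = if ("block" %in% names(d)) d$block else NULL,
                  specimen_id = specimen_id)
}

#' Write configurations as classic TPS text
#'
#' One `LM3=` block per specimen with an `ID=` record.
#'
#' @param configs List of `landmark_config` objects.
#' @param path Output path.
#' @export
write_tps <- function(configs, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (cfg in configs) {
    writeLines(sprintf("LM3=%d", nrow(cfg$points)), con)
    writeLines(sprintf("%s %s %s", .fmt_num(cfg$points[, 1]),
                       .fmt_num(cfg$points[, 2]), .fmt_num(cfg$points[, 3])),
               con)
    writeLines(sprintf("ID=%s", cfg$specimen_id), con)
  }
  invisible(path)
}

#' Read classic TPS text
#'
#' @param path Input path.
#' @param labels Optional labels applied to every configuration (defaults
#'   to the canonical scheme when the point count matches, else generic).
#' @return List of `landmark_config` objects.
#' @export
read_tps <- function(path, labels = NULL) {
  lines <- trimws(readLines(path))
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^LM3?=", lines[i])) {
      k <- as.integer(sub("^LM3?=", "", lines[i]))
      coords <- lines[(i + 1):(i + k)]
      P <- t(vapply(strsplit(coords, "\\s+"),
                    function(p) as.numeric(p[1:3]), numeric(3)))
      i <- i + k + 1L
      id <- sprintf("tps%02d", length(out) + 1L)
      if (i <= length(lines) && grepl("^ID=", lines[i])) {
        id <- sub("^ID=", "", lines[i]); i <- i + 1L
      }
      labs <- labels
      if (is.null(labs) && k == 108L) labs <- otolith_scheme()$label
      out[[length(out) + 1L]] <- landmark_config(P, labs, specimen_id = id)
    } else i <- i + 1L
  }
  out
}

#' Read a landmark file of any supported format
#'
#' Dispatches on `format` (or the file extension): Slicer `.fcsv`,
#' Slicer `.mrk.json`, plain landmark CSV, or classic TPS text (which may
#' hold several specimens — the first is returned; use [read_tps()] for
#' all).
#'
#' @param path Input path.
#' @param format One of `"auto"`, `"fcsv"`, `"mrk.json"`, `"csv"`,
#'   `"tps"`.
#' @return A `landmark_config`.
#' @export
read_landmarks <- function(path, format = c("auto", "fcsv", "mrk.json",
                                            "csv", "tps")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mrk\\.json$", path)) "mrk.json"
    else tolower(tools::file_ext(path))
  }
  switch(format,
         fcsv = read_fcsv(path),
         "mrk.json" = read_mrk_json(path),
         json = read_mrk_json(path),
         csv = read_landmark_csv(path),
         tps = read_tps(path)[[1]],
         stop("unsupported landmark format: ", format))
}
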