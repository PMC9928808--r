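# Minimal readers/writers for bone surface points (ASCII PLY, OBJ) and
# landmark JSON files. Only vertex data is consumed; faces in OBJ/PLY
# files are read when present (needed for solid inertia) but optional.

#' Read bone surface points from PLY or OBJ
#'
#' Reads vertex coordinates (and triangular faces, when present) from an
#' ASCII PLY or a Wavefront OBJ file. Binary PLY is not supported.
#'
#' @param path File path ending in `.ply` or `.obj`.
#' @return List with `points` (n x 3 matrix) and `faces` (m x 3 integer
#'   matrix of 1-based indices, or `NULL`).
#' @export
read_bone_points <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path, warn = FALSE)
  if (ext == "obj") {
    vl <- grep("^v ", lines, value = TRUE)
    pts <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x)
      as.numeric(x[2:4])))
    fl <- grep("^f ", lines, value = TRUE)
    faces <- if (length(fl)) {
      do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x)
        as.integer(sub("/.*", "", x[2:4]))))
    } else NULL
    return(list(points = pts, faces = faces))
  }
  if (ext != "ply") stop("unsupported geometry format: .", ext, call. = FALSE)
  if (!grepl("^ply", lines[1]))
    stop(path, " is not a PLY file", call. = FALSE)
  if (!any(grepl("format ascii", lines)))
    stop("only ASCII PLY is supported", call. = FALSE)
  hdr_end <- grep("^end_header", lines)[1]
  nv <- as.integer(sub(".*element vertex ", "",
                       grep("element vertex", lines, value = TRUE)[1]))
  nf_line <- grep("element face", lines, value = TRUE)
  nf <- if (length(nf_line)) as.integer(sub(".*element face ", "",
                                            nf_line[1])) else 0L
  body <- lines[(hdr_end + 1L):length(lines)]
  pts <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                               function(x) as.numeric(x[1:3])))
  faces <- NULL
  if (nf > 0L) {
    faces <- do.call(rbind,
                     lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                            function(x) as.integer(x[2:4]) + 1L))
  }
  list(points = pts, faces = faces)
}

#' Write points (and optional faces) to ASCII PLY
#'
#' @param points n x 3 matrix.
#' @param path Output `.ply` path.
#' @param faces Optional m x 3 matrix of 1-based triangle indices.
#' @return `path`, invisibly.
#' @export
write_bone_points <- function(points, path, faces = NULL) {
  points <- as.matrix(points)
  hdr <- c("ply", "format ascii 1.0",
           paste("element vertex", nrow(points)),
           "property float x", "property float y", "property float z")
  if (!is.null(faces))
    hdr <- c(hdr, paste("element face", nrow(faces)),
             "property list uchar int vertex_indices")
  hdr <- c(hdr, "end_header")
  body <- apply(points, 1, function(p) paste(sprintf("%.8g", p),
                                             collapse = " "))
  if (!is.null(faces))
    body <- c(body, apply(faces, 1, function(f)
      paste(c(3L, f - 1L), collapse = " ")))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read anatomical landmarks from JSON
#'
#' Landmark files hold named points (length-3 arrays) and direction vectors
#' used by the frame builders: `notch_apex`, `plateau_centers` (2 x 3),
#' `eminence_midpoint`, `ridge_direction`, and optional orientation hints.
#'
#' @param path JSON file path.
#' @return Named list with numeric vectors/matrices.
#' @export
read_landmarks <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$plateau_centers))
    obj$plateau_centers <- matrix(unlist(obj$plateau_centers),
                                  ncol = 3, byrow = !is.matrix(
                                    obj$plateau_centers))
  obj
}

#' Write anatomical landmarks to JSON
#' @param landmarks Named list of numeric vectors/matrices.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  lm <- lapply(landmarks, function(v) {
    if (is.matrix(v)) apply(v, 1, as.numeric, simplify = FALSE)
    else as.numeric(v)
  })
  jsonlite::write_json(lm, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
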