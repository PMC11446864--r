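# Mesh and cloud file I/O: STL (binary + ASCII) and PLY (ASCII, optional
# per-vertex scalar). No mesh package exists in the R dependency set, so the
# readers/writers are implemented here. Coordinates are assumed mm (STL/PLY
# carry no units); the assumption is recorded in metadata.

#' Load a surface mesh from STL or PLY
#'
#' Reads binary or ASCII STL (auto-detected) or ASCII PLY. Duplicate vertices
#' are merged within 1e-6 mm, stitching the per-facet vertex soup that STL
#' stores into a connected mesh.
#'
#' @param path path to a `.stl` or `.ply` file
#' @param merge_tol vertex merge tolerance in mm
#' @return a `triangle_mesh`; `metadata$source` records the path, and
#'   `metadata$units` the mm assumption
#' @export
load_mesh <- function(path, merge_tol = 1e-6) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  m <- if (ext == "ply") read_ply(path)
  else read_stl(path)
  if (nrow(m$vertices) == 0) stop("empty mesh in file: ", path)
  m <- merge_vertices(m, merge_tol)
  m$metadata$source <- path
  m$metadata$units <- "mm (assumed; STL/PLY carry no units)"
  m
}

#' Save a surface mesh to STL or PLY
#'
#' @param mesh a non-empty `triangle_mesh`
#' @param path output path; format chosen by extension (`.stl` or `.ply`)
#' @param ascii for STL, write the ASCII dialect instead of binary
#' @param scalar optional per-vertex scalar written to PLY as property
#'   `quality` (ignored for STL)
#' @return invisibly, the path
#' @export
save_mesh <- function(mesh, path, ascii = FALSE, scalar = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$vertices) == 0 || nrow(mesh$faces) == 0)
    stop("refusing to write an empty mesh")
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") write_ply(mesh$vertices, mesh$faces, path, scalar = scalar)
  else if (ascii) write_stl_ascii(mesh, path)
  else write_stl_binary(mesh, path)
  invisible(path)
}

merge_vertices <- function(m, tol = 1e-6) {
  v <- m$vertices
  if (nrow(v) == 0) return(m)
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  remap <- match(key, key[first])
  newv <- v[first, , drop = FALSE]
  newf <- matrix(remap[m$faces], ncol = 3)
  degen <- newf[, 1] == newf[, 2] | newf[, 1] == newf[, 3] |
    newf[, 2] == newf[, 3]
  triangle_mesh(newv, newf[!degen, , drop = FALSE], m$metadata)
}

# --- STL -------------------------------------------------------------------

read_stl <- function(path) {
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", n = min(84, size))
  if (length(header) < 15)
    stop("STL format error: file truncated at byte ", length(header),
         " (need at least 84-byte binary header or an ASCII 'solid' block)")
  # binary iff declared triangle count matches the file size
  is_binary <- FALSE
  if (length(header) == 84) {
    ntri <- readBin(header[81:84], "integer", size = 4, endian = "little")
    if (!is.na(ntri) && ntri >= 0 && size == 84 + 50 * as.numeric(ntri))
      is_binary <- TRUE
  }
  if (is_binary) {
    ntri <- readBin(header[81:84], "integer", size = 4, endian = "little")
    body <- readBin(con, "raw", n = size - 84)
    if (length(body) != 50 * ntri)
      stop("STL format error: truncated binary body at byte ",
           84 + length(body), " (expected ", 50 * ntri, " bytes)")
    idx <- rep(seq_len(ntri) - 1L, each = 36) * 50L +
      rep(13:48, times = ntri)  # skip 12-byte normal, keep 36 vertex bytes
    coords <- readBin(body[idx], "numeric", size = 4, n = 9 * ntri,
                      endian = "little")
    verts <- matrix(coords, ncol = 3, byrow = TRUE)
    faces <- matrix(seq_len(3 * ntri), ncol = 3, byrow = TRUE)
    triangle_mesh(verts, faces)
  } else {
    txt <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) stop("STL format error: ", e$message))
    if (length(txt) == 0 || !grepl("^\\s*solid", txt[1]))
      stop("STL format error at byte 0: neither a valid binary STL ",
           "(size mismatch) nor an ASCII 'solid' header")
    vlines <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (length(vlines) %% 3 != 0)
      stop("STL format error: ASCII vertex count ", length(vlines),
           " is not a multiple of 3 (truncated facet?)")
    nums <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                                  function(x) as.numeric(x[2:4])))
    if (anyNA(nums)) stop("STL format error: unparsable vertex coordinates")
    ntri <- nrow(nums) / 3
    faces <- matrix(seq_len(3 * ntri), ncol = 3, byrow = TRUE)
    triangle_mesh(nums, faces)
  }
}

write_stl_binary <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  ntri <- nrow(f)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80)), con)
  writeBin(as.integer(ntri), con, size = 4, endian = "little")
  # facet normal (unit) + 3 vertices as float32 + 2-byte attribute count
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  e1 <- p2 - p1
  e2 <- p3 - p1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  block <- matrix(0, nrow = ntri, ncol = 12)
  block[, 1:3] <- nrm
  block[, 4:6] <- p1
  block[, 7:9] <- p2
  block[, 10:12] <- p3
  floats <- writeBin(as.vector(t(block)), raw(), size = 4, endian = "little")
  rec <- matrix(as.raw(0), nrow = 50, ncol = ntri)
  rec[1:48, ] <- matrix(floats, nrow = 48)
  writeBin(as.vector(rec), con)
  invisible(path)
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid osteomatch", con)
  for (i in seq_len(nrow(f))) {
    tri <- v[f[i, ], , drop = FALSE]
    writeLines(c("  facet normal 0 0 0", "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g",
                         tri[, 1], tri[, 2], tri[, 3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid osteomatch", con)
  invisible(path)
}

# --- PLY -------------------------------------------------------------------

write_ply <- function(vertices, faces, path, scalar = NULL) {
  n <- nrow(vertices)
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0", "comment written by osteomatch",
           sprintf("element vertex %d", n),
           "property double x", "property double y", "property double z")
  if (!is.null(scalar)) {
    stopifnot(length(scalar) == n)
    hdr <- c(hdr, "property double quality")
  }
  hdr <- c(hdr, sprintf("element face %d", nrow(faces)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  if (is.null(scalar)) {
    writeLines(sprintf("%.17g %.17g %.17g",
                       vertices[, 1], vertices[, 2], vertices[, 3]), con)
  } else {
    writeLines(sprintf("%.17g %.17g %.17g %.17g",
                       vertices[, 1], vertices[, 2], vertices[, 3], scalar),
               con)
  }
  if (nrow(faces) > 0)
    writeLines(sprintf("3 %d %d %d",
                       faces[, 1] - 1L, faces[, 2] - 1L, faces[, 3] - 1L), con)
  invisible(path)
}

read_ply <- function(path) {
  txt <- readLines(path, warn = FALSE)
  end_h <- match("end_header", trimws(txt))
  if (is.na(end_h)) stop("PLY format error: no end_header")
  hdr <- txt[seq_len(end_h)]
  if (!any(grepl("^format ascii", hdr)))
    stop("PLY format error: only ASCII PLY is supported")
  nvert <- as.integer(sub("element vertex ", "",
                          grep("^element vertex ", hdr, value = TRUE)[1]))
  nface_line <- grep("^element face ", hdr, value = TRUE)
  nface <- if (length(nface_line)) as.integer(sub("element face ", "",
                                                  nface_line[1])) else 0L
  # vertex property names, in order
  vstart <- grep("^element vertex ", hdr)[1]
  vend <- if (length(grep("^element ", hdr)) > 1)
    grep("^element ", hdr)[2] else end_h
  props <- sub("^property \\S+ ", "",
               grep("^property ", hdr[vstart:vend], value = TRUE))
  body <- txt[(end_h + 1):length(txt)]
  if (length(body) < nvert + nface)
    stop("PLY format error: body truncated (", length(body), " lines, need ",
         nvert + nface, ")")
  vdat <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nvert)]), "\\s+"),
                                as.numeric))
  verts <- vdat[, match(c("x", "y", "z"), props), drop = FALSE]
  scalar <- if ("quality" %in% props) vdat[, match("quality", props)] else NULL
  faces <- if (nface > 0) {
    fdat <- do.call(rbind,
                    lapply(strsplit(trimws(body[nvert + seq_len(nface)]),
                                    "\\s+"), as.numeric))
    if (any(fdat[, 1] != 3)) stop("PLY format error: non-triangular face")
    matrix(as.integer(fdat[, 2:4]) + 1L, ncol = 3)
  } else matrix(integer(0), ncol = 3)
  m <- triangle_mesh(verts, faces)
  if (!is.null(scalar)) m$metadata$vertex_scalar <- scalar
  m
}

#' Save a point cloud as ASCII PLY
#'
#' The scalar field (if any) is written as per-vertex property `quality`,
#' readable by standard cloud viewers for colorimetric inspection.
#'
#' @param cloud a `point_cloud`
#' @param path output `.ply` path
#' @return invisibly, the path
#' @export
save_cloud <- function(cloud, path) {
  stopifnot(inherits(cloud, "point_cloud"))
  write_ply(cloud$points, matrix(integer(0), ncol = 3), path,
            scalar = cloud$scalar)
  invisible(path)
}

#' Load a point cloud from ASCII PLY
#' @param path a `.ply` file with vertex elements (faces ignored)
#' @return a `point_cloud`; property `quality`, when present, becomes the
#'   scalar field
#' @export
load_cloud <- function(path) {
  m <- read_ply(path)
  point_cloud(m$vertices, scalar = m$metadata$vertex_scalar,
              metadata = list(source = path))
}
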