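#' CT attenuation volume
#'
#' A 3-D grid of attenuation values (Hounsfield units) with per-axis voxel
#' spacing and a physical origin, both in mm. Voxel `[i, j, k]` is centred at
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param voxels 3-D numeric array of HU values
#' @param spacing length-3 positive numeric, mm per voxel along each axis
#' @param origin length-3 numeric, mm
#' @param provenance free-form list (acquisition metadata: kV, slice
#'   thickness/interval, source series, ...)
#' @return an object of class `ct_volume`
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                      provenance = list()) {
  if (!is.array(voxels) || length(dim(voxels)) != 3)
    stop("voxels must be a 3-D array")
  if (length(voxels) == 0) stop("volume is empty")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)")
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin), provenance = provenance),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Load a CT volume from an NRRD file
#'
#' Supports detached-free NRRD with `raw` (little-endian) or `text` encoding
#' and types `double`, `float`, `short`, `int`, `uchar`. Spacing is taken from
#' `spacings` or the diagonal of `space directions`.
#'
#' @param path an `.nrrd` file
#' @return a `ct_volume`; header fields are kept in `provenance$header`
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  # header: lines until the first blank line
  hdr <- character(0)
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (length(line) == 0) stop("NRRD format error: no blank line ends header")
    if (nchar(line) == 0) break
    hdr <- c(hdr, line)
  }
  if (!grepl("^NRRD", hdr[1])) stop("NRRD format error: missing magic")
  fields <- hdr[grepl(":", hdr) & !grepl("^#", hdr)]
  kv <- do.call(rbind, lapply(strsplit(fields, ":\\s*"), function(x)
    c(tolower(trimws(x[1])), trimws(paste(x[-1], collapse = ":")))))
  get_field <- function(name) {
    i <- match(name, kv[, 1])
    if (is.na(i)) NA_character_ else kv[i, 2]
  }
  ndim <- as.integer(get_field("dimension"))
  if (is.na(ndim) || ndim != 3) stop("only 3-D NRRD volumes are supported")
  sizes <- as.integer(strsplit(get_field("sizes"), "\\s+")[[1]])
  type <- get_field("type")
  enc <- get_field("encoding")
  spacing <- rep(1, 3)
  if (!is.na(get_field("spacings"))) {
    spacing <- as.numeric(strsplit(get_field("spacings"), "\\s+")[[1]])
  } else if (!is.na(get_field("space directions"))) {
    dirs <- gsub("[()]", "", strsplit(get_field("space directions"),
                                      "\\)\\s*\\(")[[1]])
    dm <- do.call(rbind, lapply(strsplit(dirs, ","), as.numeric))
    spacing <- sqrt(rowSums(dm^2))
  }
  origin <- c(0, 0, 0)
  if (!is.na(get_field("space origin")))
    origin <- as.numeric(strsplit(gsub("[()]", "", get_field("space origin")),
                                  ",")[[1]])
  nvox <- prod(sizes)
  vals <- if (identical(enc, "text") || identical(enc, "ascii")) {
    scan(con, what = double(), n = nvox, quiet = TRUE)
  } else if (identical(enc, "raw")) {
    sz <- switch(type, double = 8L, float = 4L, short = 2L, int = 4L,
                 uchar = 1L, stop("unsupported NRRD type: ", type))
    what <- switch(type, double = "numeric", float = "numeric", "integer")
    readBin(con, what, n = nvox, size = sz, endian = "little",
            signed = !identical(type, "uchar"))
  } else stop("unsupported NRRD encoding: ", enc)
  if (length(vals) != nvox)
    stop("NRRD format error: expected ", nvox, " values, read ", length(vals))
  ct_volume(array(as.numeric(vals), dim = sizes), spacing, origin,
            provenance = list(header = stats::setNames(kv[, 2], kv[, 1]),
                              source = path))
}

#' Save a CT volume (or integer label mask) as NRRD
#'
#' @param vol a `ct_volume`, or a `segmentation_mask` (written as int labels)
#' @param path output `.nrrd` path
#' @param encoding `"raw"` (little-endian) or `"text"`
#' @param type element type: `"double"`, `"short"` or `"int"`
#' @return invisibly, the path
#' @export
save_volume <- function(vol, path, encoding = c("raw", "text"),
                        type = "double") {
  encoding <- match.arg(encoding)
  if (inherits(vol, "segmentation_mask")) {
    vol <- ct_volume(vol$labels + 0.0, vol$spacing, vol$origin)
    type <- "int"
  }
  stopifnot(inherits(vol, "ct_volume"))
  d <- dim(vol$voxels)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "# written by osteomatch",
           sprintf("type: %s", type),
           "dimension: 3",
           sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
           sprintf("spacings: %.9g %.9g %.9g", vol$spacing[1], vol$spacing[2],
                   vol$spacing[3]),
           sprintf("encoding: %s", encoding),
           "endian: little", "")
  writeLines(hdr, con, sep = "\n")
  v <- as.vector(vol$voxels)
  if (encoding == "text") {
    writeLines(paste(format(v, digits = 17, trim = TRUE, scientific = FALSE),
                     collapse = " "), con)
  } else {
    sz <- switch(type, double = 8L, short = 2L, int = 4L,
                 stop("unsupported write type: ", type))
    if (type == "double") writeBin(v, con, size = sz, endian = "little")
    else writeBin(as.integer(round(v)), con, size = sz, endian = "little")
  }
  invisible(path)
}
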