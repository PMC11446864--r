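#' Triangle mesh
#'
#' A surface mesh of triangular faces with vertex coordinates in millimetres.
#' Face indices are 1-based rows into the vertex matrix. Degenerate faces
#' (repeated vertex index within a face) are rejected.
#'
#' @param vertices numeric matrix (n x 3), coordinates in mm
#' @param faces integer matrix (m x 3) of 1-based vertex indices
#' @param metadata named list of free-form provenance (source file, fragment
#'   id, units note, generator parameters)
#' @return an object of class `triangle_mesh`
#' @export
triangle_mesh <- function(vertices, faces, metadata = list()) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (nrow(vertices) > 0) {
    if (ncol(vertices) != 3) stop("vertices must have 3 columns")
    if (nrow(vertices) < 3) stop("non-empty mesh needs at least 3 vertices")
    if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  }
  if (nrow(faces) > 0) {
    if (min(faces) < 1 || max(faces) > nrow(vertices))
      stop("face indices out of range [1, ", nrow(vertices), "]")
    degen <- faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
      faces[, 2] == faces[, 3]
    if (any(degen))
      stop("degenerate face(s) with repeated vertex index at row(s): ",
           paste(utils::head(which(degen), 5), collapse = ", "))
  }
  structure(list(vertices = vertices, faces = faces, metadata = metadata),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Point cloud
#'
#' N points in mm with an optional per-point scalar field (roughness or
#' distance) and an optional per-point index into a parent cloud or mesh.
#'
#' @param points numeric matrix (n x 3), mm
#' @param scalar optional numeric vector of length n (NA marks invalid)
#' @param parent_index optional integer vector of length n
#' @param metadata named list of provenance
#' @return an object of class `point_cloud`
#' @export
point_cloud <- function(points, scalar = NULL, parent_index = NULL,
                        metadata = list()) {
  points <- as.matrix(points)
  if (length(points) == 0) points <- matrix(numeric(0), ncol = 3)
  if (ncol(points) != 3) stop("points must have 3 columns")
  if (!all(is.finite(points))) stop("point coordinates must be finite")
  n <- nrow(points)
  if (!is.null(scalar) && length(scalar) != n)
    stop("scalar field length ", length(scalar), " != point count ", n)
  if (!is.null(parent_index)) {
    parent_index <- as.integer(parent_index)
    if (length(parent_index) != n)
      stop("parent_index length ", length(parent_index), " != point count ", n)
  }
  structure(list(points = points, scalar = scalar,
                 parent_index = parent_index, metadata = metadata),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points%s%s\n", nrow(x$points),
              if (!is.null(x$scalar)) ", with scalar field" else "",
              if (!is.null(x$parent_index)) ", with parent index" else ""))
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud a `point_cloud`
#' @return integer count
#' @export
n_points <- function(cloud) nrow(cloud$points)

#' Rigid transform
#'
#' A proper rigid motion: rotation (orthonormal, det +1) plus translation in
#' mm. Maps a point p to `R p + t`.
#'
#' @param rotation 3x3 rotation matrix
#' @param translation length-3 numeric, mm
#' @param tol orthonormality tolerance
#' @return an object of class `rigid_transform`
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            tol = 1e-9) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3, 3)) || length(translation) != 3)
    stop("rotation must be 3x3 and translation length 3")
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > tol)
    stop(sprintf("rotation is not orthonormal (max |R'R - I| = %.3g)", err))
  if (abs(det(rotation) - 1) > tol)
    stop(sprintf("rotation determinant %.12f != +1 (improper transform)",
                 det(rotation)))
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Identity rigid transform
#' @return a `rigid_transform`
#' @export
rt_identity <- function() rigid_transform()

#' Compose rigid transforms
#'
#' `rt_compose(T2, T1)` is the transform that applies `T1` first, then `T2`.
#'
#' @param T2,T1 `rigid_transform` objects
#' @return the composed `rigid_transform`
#' @export
rt_compose <- function(T2, T1) {
  rigid_transform(T2$rotation %*% T1$rotation,
                  as.numeric(T2$rotation %*% T1$translation) + T2$translation)
}

#' Invert a rigid transform
#' @param tr a `rigid_transform`
#' @return the inverse `rigid_transform`
#' @export
rt_invert <- function(tr) {
  Rt <- t(tr$rotation)
  rigid_transform(Rt, as.numeric(-Rt %*% tr$translation))
}

#' Apply a rigid transform to raw coordinates
#' @param tr a `rigid_transform`
#' @param points numeric matrix (n x 3)
#' @return transformed matrix (n x 3)
#' @export
rt_apply <- function(tr, points) {
  points <- as.matrix(points)
  sweep(points %*% t(tr$rotation), 2, tr$translation, "+")
}

#' Rotation angle of a rigid transform
#'
#' The geodesic rotation angle in degrees, useful for pose-error reporting.
#'
#' @param tr a `rigid_transform`
#' @return angle in degrees
#' @export
rt_angle_deg <- function(tr) {
  c_ang <- (sum(diag(tr$rotation)) - 1) / 2
  acos(max(-1, min(1, c_ang))) * 180 / pi
}

#' Transform a point cloud
#'
#' Applies `p -> R p + t` to every point; scalar field and parent indices are
#' carried through unchanged.
#'
#' @param cloud a `point_cloud`
#' @param tr a `rigid_transform`
#' @return the transformed `point_cloud`
#' @export
apply_transform <- function(cloud, tr) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (!inherits(tr, "rigid_transform"))
    tr <- rigid_transform(tr$rotation, tr$translation)  # re-validate
  point_cloud(rt_apply(tr, cloud$points), scalar = cloud$scalar,
              parent_index = cloud$parent_index, metadata = cloud$metadata)
}

#' Random rigid transform
#'
#' Uniform random rotation (QR of a Gaussian matrix, sign-corrected) plus a
#' translation drawn uniformly from a cube. Used for scatter poses and tests.
#'
#' @param seed integer seed
#' @param max_translation half-width of the translation cube, mm
#' @return a `rigid_transform`
#' @export
random_rigid_transform <- function(seed, max_translation = 100) {
  with_seed(seed, {
    M <- matrix(rnorm(9), 3, 3)
    qr_d <- qr(M)
    Q <- qr.Q(qr_d)
    d <- sign(diag(qr.R(qr_d)))
    Q <- Q %*% diag(d)
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    rigid_transform(Q, runif(3, -max_translation, max_translation))
  })
}

#' Nearest-neighbour distances between clouds
#'
#' For every point of `query`, the Euclidean distance (mm) to its nearest
#' point in `reference`, computed through a kd-tree. The matched reference
#' indices are attached as attribute `"index"`.
#'
#' @param query,reference `point_cloud` objects (both non-empty)
#' @return numeric vector of distances, one per query point
#' @export
nearest_distances <- function(query, reference) {
  stopifnot(inherits(query, "point_cloud"), inherits(reference, "point_cloud"))
  if (n_points(reference) == 0) stop("reference cloud is empty")
  if (n_points(query) == 0) stop("query cloud is empty")
  res <- cpp_nearest(reference$points, query$points)
  structure(res$dist, index = res$index)
}

#' Merge (concatenate) point clouds
#'
#' Plain concatenation, no deduplication: the merged count is the sum of the
#' input counts. Scalar/parent fields are kept only if present on all inputs.
#'
#' @param ... `point_cloud` objects
#' @return the concatenated `point_cloud`
#' @export
merge_clouds <- function(...) {
  clouds <- list(...)
  stopifnot(all(vapply(clouds, inherits, logical(1), "point_cloud")))
  pts <- do.call(rbind, lapply(clouds, function(cl) cl$points))
  scal <- if (all(vapply(clouds, function(cl) !is.null(cl$scalar), logical(1))))
    unlist(lapply(clouds, function(cl) cl$scalar)) else NULL
  point_cloud(pts, scalar = scal)
}

# --- mesh measures ---------------------------------------------------------

#' Total surface area of a mesh (mm^2)
#' @param mesh a `triangle_mesh`
#' @return area in mm^2
#' @export
mesh_area <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(0)
  sum(triangle_areas(mesh))
}

triangle_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Enclosed volume of a closed mesh (mm^3)
#'
#' Signed volume by the divergence theorem; meaningful for watertight,
#' consistently oriented surfaces. The absolute value is returned.
#'
#' @param mesh a `triangle_mesh`
#' @return volume in mm^3
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  det6 <- p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
          p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
          p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  abs(sum(det6)) / 6
}

#' Watertightness check
#'
#' A closed 2-manifold has every undirected edge shared by exactly two faces.
#'
#' @param mesh a `triangle_mesh`
#' @return TRUE if every edge is shared by exactly 2 faces
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}
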