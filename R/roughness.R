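#' Per-point roughness scalar field
#'
#' For every point, the orthogonal distance (mm) to the least-squares plane
#' fitted to its neighbours within `kernel_radius` — the query point itself is
#' excluded from the fit (including it would bias roughness low). Points with
#' fewer than 3 neighbours, or with a numerically collinear neighbour set,
#' receive `NA`, which is treated as below any threshold downstream so that
#' isolated outliers never enter fracture surfaces.
#'
#' Fractured cortical surfaces carry markedly higher roughness than intact
#' cortical bone, which is what makes threshold-based fracture-surface
#' segmentation possible.
#'
#' @param cloud a `point_cloud`
#' @param kernel_radius neighbourhood radius in mm (default 2.0: several
#'   inter-point spacings at the protocol's 100 000-point density on a
#'   femur-scale surface, yet below fracture-face feature size)
#' @return the input cloud with `scalar` set to the roughness field
#' @export
roughness <- function(cloud, kernel_radius = 2.0) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (kernel_radius <= 0) stop("kernel_radius must be positive")
  r <- cpp_roughness(cloud$points, kernel_radius)
  out <- cloud
  out$scalar <- as.numeric(r)
  out$metadata$roughness_kernel_radius <- kernel_radius
  out
}

#' Segment the fracture surface of a fragment cloud
#'
#' Keeps exactly the points whose roughness scalar is at or above `threshold`
#' (default 1.0, in cloud units = mm); lower-roughness points — the smooth
#' cortical surface — are dropped. The indices of the retained points in the
#' parent cloud are recorded so that a transform estimated on the fracture
#' surface can later be transferred to the full fragment.
#'
#' @param cloud_with_roughness a `point_cloud` carrying a roughness scalar
#'   field (see [roughness()])
#' @param threshold minimum roughness retained, mm (default 1.0)
#' @return a `fracture_surface`: list with `cloud` (the retained subset, its
#'   `parent_index` pointing into the input), `parent_index`, and
#'   `threshold_used`
#' @export
segment_fracture <- function(cloud_with_roughness, threshold = 1.0) {
  stopifnot(inherits(cloud_with_roughness, "point_cloud"))
  sc <- cloud_with_roughness$scalar
  if (is.null(sc))
    stop("cloud has no scalar field; run roughness() first")
  keep <- which(!is.na(sc) & sc >= threshold)
  # compose parent indices if the input is itself a subset of another cloud
  parent <- if (!is.null(cloud_with_roughness$parent_index))
    cloud_with_roughness$parent_index[keep] else keep
  sub <- point_cloud(cloud_with_roughness$points[keep, , drop = FALSE],
                     scalar = sc[keep], parent_index = parent,
                     metadata = cloud_with_roughness$metadata)
  structure(list(cloud = sub, parent_index = parent,
                 threshold_used = threshold),
            class = "fracture_surface")
}

#' @export
print.fracture_surface <- function(x, ...) {
  cat(sprintf("<fracture_surface> %d points at roughness >= %g mm\n",
              n_points(x$cloud), x$threshold_used))
  invisible(x)
}
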