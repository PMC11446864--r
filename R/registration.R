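# Registration and iterative merge: correspondence-seeded coarse alignment,
# trimmed ICP refinement on fracture surfaces, transform transfer to the full
# fragments, and sequential whole-bone reassembly.

#' Least-squares rigid transform from point correspondences
#'
#' Closed-form Kabsch/Umeyama solution: the proper rigid transform (R, t)
#' minimizing `sum ||R mov_i + t - ref_i||^2`, via SVD of the cross-covariance
#' with determinant correction. At least 3 non-collinear pairs are required.
#'
#' @param ref_points,mov_points matched coordinate matrices (n x 3, n >= 3)
#' @return a `rigid_transform` mapping `mov` onto `ref`
#' @export
rigid_from_correspondences <- function(ref_points, mov_points) {
  ref_points <- as.matrix(ref_points)
  mov_points <- as.matrix(mov_points)
  n <- nrow(ref_points)
  if (n < 3 || nrow(mov_points) != n)
    stop("need >= 3 correspondence pairs of equal length (got ", n, " / ",
         nrow(mov_points), ")")
  cr <- colMeans(ref_points)
  cm <- colMeans(mov_points)
  X <- sweep(mov_points, 2, cm)
  Y <- sweep(ref_points, 2, cr)
  H <- crossprod(X, Y)  # 3x3 cross-covariance
  sv <- svd(H)
  # collinear/degenerate: rank of the centred configurations < 2
  if (sv$d[2] <= max(sv$d[1], .Machine$double.eps) * 1e-8)
    stop("degenerate (collinear) correspondence configuration: ",
         "rank of cross-covariance < 2")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cr - as.numeric(R %*% cm)
  rigid_transform(R, t_vec)
}

#' Trimmed iterative-closest-point refinement
#'
#' Point-to-point ICP with the "most distant points excluded" rule: each
#' iteration matches every (transformed) moving point to its nearest
#' reference point, drops pairs beyond `max_corr_dist`, keeps the best
#' `trim_keep_fraction` of the remainder by distance, and re-solves the rigid
#' least-squares alignment on the kept pairs. Iteration stops when the
#' relative change of the trimmed RMS falls below `rel_tol`, when `max_iter`
#' is reached, or when the trimmed RMS would increase (the previous transform
#' is then kept, so the reported objective is non-increasing).
#'
#' @param ref reference (fixed) `point_cloud`
#' @param mov moving `point_cloud`
#' @param init initial `rigid_transform` (e.g. from
#'   [rigid_from_correspondences()]); default identity
#' @param params list overriding any of `max_iter` (50), `rel_tol` (1e-6),
#'   `trim_keep_fraction` (0.8), `max_corr_dist` (5 mm; `Inf` disables)
#' @return an `icp_result`: `transform` (composed with `init`), `final_rms`
#'   (mm, trimmed), `iterations`, `converged`, `kept_fraction`, `rms_history`
#' @export
icp_refine <- function(ref, mov, init = rt_identity(), params = list()) {
  stopifnot(inherits(ref, "point_cloud"), inherits(mov, "point_cloud"))
  if (n_points(ref) == 0 || n_points(mov) == 0)
    stop("ICP requires non-empty clouds")
  p <- utils::modifyList(list(max_iter = 50L, rel_tol = 1e-6,
                              trim_keep_fraction = 0.8, max_corr_dist = 5),
                         params)
  if (p$trim_keep_fraction <= 0 || p$trim_keep_fraction > 1)
    stop("trim_keep_fraction must be in (0, 1]")
  tr <- init
  best <- init           # last transform whose trimmed RMS was evaluated
  rms_hist <- numeric(0)
  kept_frac <- NA_real_
  converged <- FALSE
  for (iter in seq_len(p$max_iter)) {
    moved <- rt_apply(tr, mov$points)
    nn <- cpp_nearest(ref$points, moved)
    ok <- which(nn$dist <= p$max_corr_dist)
    if (length(ok) < 3)
      stop("ICP non-convergence: only ", length(ok), " correspondences ",
           "within max_corr_dist = ", p$max_corr_dist, " mm at iteration ",
           iter, " (min distance ", signif(min(nn$dist), 3), " mm)")
    n_keep <- max(3L, floor(p$trim_keep_fraction * length(ok)))
    kept <- ok[order(nn$dist[ok])[seq_len(n_keep)]]
    rms <- sqrt(mean(nn$dist[kept]^2))
    if (length(rms_hist) > 0 && rms > rms_hist[length(rms_hist)]) {
      tr <- best                     # objective would rise: keep previous
      converged <- TRUE
      break
    }
    best <- tr
    rms_hist <- c(rms_hist, rms)
    kept_frac <- n_keep / n_points(mov)
    if (length(rms_hist) >= 2) {
      prev <- rms_hist[length(rms_hist) - 1]
      if (abs(prev - rms) <= p$rel_tol * max(prev, .Machine$double.eps)) {
        converged <- TRUE
        break
      }
    }
    step <- rigid_from_correspondences(
      ref$points[nn$index[kept], , drop = FALSE],
      moved[kept, , drop = FALSE])
    tr <- rt_compose(step, tr)
  }
  structure(list(transform = best,
                 final_rms = rms_hist[length(rms_hist)],
                 iterations = length(rms_hist),
                 converged = converged, kept_fraction = kept_frac,
                 rms_history = rms_hist, params = p),
            class = "icp_result")
}

#' @export
print.icp_result <- function(x, ...) {
  cat(sprintf(
    "<icp_result> rms %.4g mm after %d iteration(s), %sconverged, kept %.0f%%\n",
    x$final_rms, x$iterations, if (x$converged) "" else "NOT ",
    100 * x$kept_fraction))
  invisible(x)
}

#' Re-associate one fragment pair
#'
#' The per-pair protocol: a coarse transform from the operator's
#' correspondence points; trimmed-ICP refinement restricted to the two
#' fracture surfaces; the refined transform copied onto the *full* moving
#' fragment; and the reference and transformed fragments concatenated into a
#' merged cloud (no deduplication — the merged count is exactly
#' `N_ref + N_mov`).
#'
#' @param ref_fragment,mov_fragment full fragment `point_cloud`s
#' @param ref_surface,mov_surface their `fracture_surface`s (parent indices
#'   must address the corresponding fragment)
#' @param correspondences list with matrices `ref` and `mov` (>= 3 matched
#'   points, mm, in each fragment's own frame)
#' @param params ICP parameter overrides, see [icp_refine()]
#' @return list: `merged` cloud, `record` (`icp_result`), `transform` (the
#'   full mov-to-ref transform actually applied)
#' @export
reassociate_pair <- function(ref_fragment, mov_fragment, ref_surface,
                             mov_surface, correspondences, params = list()) {
  stopifnot(inherits(ref_surface, "fracture_surface"),
            inherits(mov_surface, "fracture_surface"))
  if (max(ref_surface$parent_index) > n_points(ref_fragment) ||
      max(mov_surface$parent_index) > n_points(mov_fragment))
    stop("fracture surface parent indices do not address their fragment")
  coarse <- rigid_from_correspondences(correspondences$ref,
                                       correspondences$mov)
  rec <- icp_refine(ref_surface$cloud, mov_surface$cloud, init = coarse,
                    params = params)
  moved <- apply_transform(mov_fragment, rec$transform)
  merged <- merge_clouds(ref_fragment, moved)
  list(merged = merged, record = rec, transform = rec$transform)
}

#' Match plan
#'
#' The operator's declaration of which fragment pairs share a fracture
#' surface, in accumulation order, with at least 3 (typically 4)
#' correspondence point pairs per step. Correspondence coordinates are given
#' in each fragment's own input frame.
#'
#' @param steps list of steps; each a list with `ref` and `mov` (fragment
#'   ids), `ref_points` and `mov_points` (n x 3 matrices, n >= 3), and
#'   optional `params` (per-step ICP overrides)
#' @return a `match_plan`
#' @export
match_plan <- function(steps) {
  for (i in seq_along(steps)) {
    s <- steps[[i]]
    if (is.null(s$ref) || is.null(s$mov))
      stop("plan step ", i, ": missing ref/mov fragment id")
    rp <- as.matrix(s$ref_points)
    mp <- as.matrix(s$mov_points)
    if (nrow(rp) < 3 || nrow(rp) != nrow(mp))
      stop("plan step ", i, ": need >= 3 correspondence pairs of equal count")
    for (m in list(rp, mp)) {
      cs <- svd(scale(m, scale = FALSE))$d
      if (cs[2] <= max(cs[1], .Machine$double.eps) * 1e-8)
        stop("plan step ", i, ": collinear correspondence points")
    }
    steps[[i]]$ref_points <- rp
    steps[[i]]$mov_points <- mp
  }
  structure(list(steps = steps), class = "match_plan")
}

#' Read / write a match plan as JSON
#'
#' @param path a `.json` file
#' @return [load_match_plan()] returns a `match_plan`
#' @export
load_match_plan <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  steps <- lapply(raw$steps, function(s)
    list(ref = s$ref, mov = s$mov,
         ref_points = do.call(rbind, lapply(s$ref_points, unlist)),
         mov_points = do.call(rbind, lapply(s$mov_points, unlist))))
  match_plan(steps)
}

#' @rdname load_match_plan
#' @param plan a `match_plan`
#' @return [save_match_plan()] returns the path, invisibly
#' @export
save_match_plan <- function(plan, path) {
  steps <- data.frame(ref = vapply(plan$steps, `[[`, character(1), "ref"),
                      mov = vapply(plan$steps, `[[`, character(1), "mov"))
  steps$ref_points <- lapply(plan$steps, function(s)
    lapply(seq_len(nrow(s$ref_points)), function(i) s$ref_points[i, ]))
  steps$mov_points <- lapply(plan$steps, function(s)
    lapply(seq_len(nrow(s$mov_points)), function(i) s$mov_points[i, ]))
  jsonlite::write_json(list(steps = steps), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Sequential whole-bone reassembly
#'
#' Executes a match plan in order. The first step's reference fragment
#' anchors the assembly frame (its pose is the identity). After each
#' successful step the merged model becomes the new reference: the moving
#' fragment's fracture surface is registered against the *posed* fracture
#' surface of its declared reference fragment, and the resulting transform is
#' that fragment's final pose. A failing step is recorded and the remaining
#' plan entries continue — partial reconstruction is a valid outcome.
#'
#' @param fragments named list of `point_cloud`s (full fragments)
#' @param plan a `match_plan`; correspondence coordinates in each fragment's
#'   input frame
#' @param params list: ICP overrides plus `kernel_radius` (2 mm) and
#'   `threshold` (1 mm) used to segment fracture surfaces, and optional
#'   `surfaces` (a named list of precomputed `fracture_surface`s)
#' @return a `reassembly_result`: `merged` cloud, `poses` (final
#'   `rigid_transform` per merged fragment), `steps` (per-step diagnostics),
#'   `n_attempted`, `n_merged` (fragments incorporated, including the anchor)
#' @export
reassemble <- function(fragments, plan, params = list()) {
  stopifnot(inherits(plan, "match_plan"), length(fragments) > 0,
            !is.null(names(fragments)))
  kernel <- if (is.null(params$kernel_radius)) 2.0 else params$kernel_radius
  thr <- if (is.null(params$threshold)) 1.0 else params$threshold
  icp_params <- params[intersect(names(params),
                                 c("max_iter", "rel_tol",
                                   "trim_keep_fraction", "max_corr_dist"))]
  ids <- names(fragments)
  for (s in plan$steps)
    if (!all(c(s$ref, s$mov) %in% ids))
      stop("plan references unknown fragment id(s): ",
           paste(setdiff(c(s$ref, s$mov), ids), collapse = ", "))
  surfaces <- params$surfaces
  get_surface <- function(id) {
    if (!is.null(surfaces[[id]])) return(surfaces[[id]])
    sf <- segment_fracture(roughness(fragments[[id]], kernel), thr)
    surfaces[[id]] <<- sf
    sf
  }
  poses <- list()
  merged <- NULL
  steps_out <- list()
  n_merged <- 0L
  for (k in seq_along(plan$steps)) {
    s <- plan$steps[[k]]
    out <- tryCatch({
      if (is.null(poses[[s$ref]])) {
        if (k == 1L || n_merged == 0L) {
          poses[[s$ref]] <- rt_identity()
          merged <- fragments[[s$ref]]
          n_merged <- n_merged + 1L
        } else stop("reference fragment '", s$ref,
                    "' has not been merged yet")
      }
      pose_ref <- poses[[s$ref]]
      ref_surf <- get_surface(s$ref)
      mov_surf <- get_surface(s$mov)
      ref_surf_posed <- ref_surf
      ref_surf_posed$cloud <- apply_transform(ref_surf$cloud, pose_ref)
      corr <- list(ref = rt_apply(pose_ref, s$ref_points),
                   mov = s$mov_points)
      step_params <- utils::modifyList(icp_params,
                                       if (is.null(s$params)) list()
                                       else s$params)
      coarse <- rigid_from_correspondences(corr$ref, corr$mov)
      rec <- icp_refine(ref_surf_posed$cloud, mov_surf$cloud, init = coarse,
                        params = step_params)
      poses[[s$mov]] <- rec$transform
      moved <- apply_transform(fragments[[s$mov]], rec$transform)
      merged <- merge_clouds(merged, moved)
      n_merged <- n_merged + 1L
      list(ref = s$ref, mov = s$mov, status = "merged", record = rec)
    }, error = function(e) {
      list(ref = s$ref, mov = s$mov, status = "failed",
           message = conditionMessage(e))
    })
    steps_out[[k]] <- out
  }
  if (is.null(merged)) {
    merged <- fragments[[1]]
    poses[[ids[1]]] <- rt_identity()
    n_merged <- if (length(plan$steps) == 0) 0L else n_merged
  }
  structure(list(merged = merged, poses = poses, steps = steps_out,
                 n_attempted = length(plan$steps),
                 n_merged = n_merged,
                 fragment_ids = ids),
            class = "reassembly_result")
}

#' @export
print.reassembly_result <- function(x, ...) {
  cat(sprintf("<reassembly_result> %d/%d plan steps ok, %d fragment(s) merged, %d points\n",
              sum(vapply(x$steps, function(s) s$status == "merged",
                         logical(1))),
              x$n_attempted, x$n_merged, n_points(x$merged)))
  invisible(x)
}

#' Export a reassembly manifest (JSON) and merged cloud (PLY)
#'
#' Poses are written as 4x4 row-major homogeneous matrices.
#'
#' @param result a `reassembly_result`
#' @param dir output directory (created if needed)
#' @return invisibly, the manifest path
#' @export
save_reassembly <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  poses <- lapply(result$poses, function(tr) {
    m <- rbind(cbind(tr$rotation, tr$translation), c(0, 0, 0, 1))
    as.vector(t(m))  # row-major
  })
  manifest <- list(
    n_attempted = result$n_attempted, n_merged = result$n_merged,
    poses_row_major_4x4 = poses,
    steps = lapply(result$steps, function(s)
      list(ref = s$ref, mov = s$mov, status = s$status,
           final_rms = if (s$status == "merged") s$record$final_rms else NA,
           iterations = if (s$status == "merged") s$record$iterations else NA)))
  path <- file.path(dir, "reassembly.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  save_cloud(result$merged, file.path(dir, "merged.ply"))
  invisible(path)
}
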