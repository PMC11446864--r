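# Ground-truthed synthetic data: parametric long bones, controlled
# fragmentation with rough conforming fracture faces and known scatter poses,
# and voxelized CT stand-ins. Emulates cleaned long-bone specimens that are
# fragmented, scattered, and must be re-associated.

#' Parametric long-bone surface
#'
#' A closed, watertight surface of revolution about the z axis: a cylindrical
#' shaft that flares smoothly (smoothstep ramp over the terminal 15% of
#' length) to wider, rounded ends (ellipsoidal caps, so there is no sharp rim
#' whose mixed neighbourhoods would masquerade as fracture roughness), with
#' optional low-amplitude seeded undulation so the cortical surface is not
#' analytically flat. The bone is modelled as a cortical
#' shell: `cortical_thickness` is stored with the profile and used by
#' [fracture()] to build annular fracture faces and the endosteal surface.
#'
#' @param length total length, mm (> 4 * end_radius)
#' @param shaft_radius outer shaft radius, mm
#' @param end_radius outer radius at the flared ends, mm (>= shaft_radius)
#' @param seed integer seed (undulation phases)
#' @param cortical_thickness cortical shell thickness, mm
#' @param undulation_amplitude radial undulation amplitude, mm (< 0.05)
#' @param n_axial,n_theta tessellation resolution
#' @return a watertight `triangle_mesh`; `metadata$profile` carries the
#'   generator parameters
#' @export
make_long_bone <- function(length = 200, shaft_radius = 12, end_radius = 25,
                           seed = 1, cortical_thickness = 2.5,
                           undulation_amplitude = 0.02,
                           n_axial = 240, n_theta = 96) {
  if (shaft_radius <= 0 || end_radius < shaft_radius)
    stop("need end_radius >= shaft_radius > 0")
  if (length <= 4 * end_radius)
    stop("need length > 4 * end_radius for a recognisable long bone")
  if (undulation_amplitude >= 0.05)
    stop("undulation_amplitude must stay below 0.05 mm")
  prof <- list(length = length, shaft_radius = shaft_radius,
               end_radius = end_radius, ramp_frac = 0.15,
               cortical_thickness = cortical_thickness,
               undulation_amplitude = undulation_amplitude, seed = seed)
  und <- with_seed(seed, list(k_z = sample(2:5, 3, replace = TRUE),
                              k_t = sample(1:4, 3, replace = TRUE),
                              phase_z = runif(3, 0, 2 * pi),
                              phase_t = runif(3, 0, 2 * pi),
                              w = {a <- runif(3); a / sum(a)}))
  prof$undulation <- und
  dz <- length / n_axial
  z <- seq(dz / 3, length - dz / 3, length.out = n_axial + 1)
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  r_base <- bone_radius_profile(z, prof)
  grid <- expand.grid(theta = theta, z = z)  # theta fastest
  rr <- rep(r_base, each = n_theta) +
    bone_undulation(grid$z, grid$theta, prof)
  verts <- cbind(rr * cos(grid$theta), rr * sin(grid$theta), grid$z)
  # two pole vertices close the ends
  vbot <- nrow(verts) + 1L
  vtop <- nrow(verts) + 2L
  verts <- rbind(verts, c(0, 0, 0), c(0, 0, length))
  idx <- function(i, j) (i - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  faces <- vector("list", n_axial + 2)
  for (i in seq_len(n_axial)) {
    j <- seq_len(n_theta)
    a <- idx(i, j); b <- idx(i, j + 1); cc <- idx(i + 1, j); d <- idx(i + 1, j + 1)
    faces[[i]] <- rbind(cbind(a, b, d), cbind(a, d, cc))
  }
  j <- seq_len(n_theta)
  faces[[n_axial + 1]] <- cbind(idx(1, j + 1), idx(1, j), vbot)
  faces[[n_axial + 2]] <- cbind(idx(n_axial + 1, j),
                                idx(n_axial + 1, j + 1), vtop)
  triangle_mesh(verts, do.call(rbind, faces),
                metadata = list(profile = prof, generator = "make_long_bone"))
}

# Outer radius at height z (without undulation): rounded ellipsoidal end
# caps (no sharp rim), a smoothstep ramp from end to shaft radius over the
# terminal 15% of length, and a cylindrical shaft between.
bone_radius_profile <- function(z, prof) {
  L <- prof$length
  cap <- 0.06 * L
  ramp <- prof$ramp_frac * L
  smoothstep <- function(t) {
    t <- pmin(1, pmax(0, t))
    t * t * (3 - 2 * t)
  }
  zm <- pmin(z, L - z)                  # distance to the nearest end
  r_cap <- prof$end_radius *
    sqrt(pmax(0, 1 - (1 - pmin(zm, cap) / cap)^2))
  t_ramp <- smoothstep((zm - cap) / (ramp - cap))
  r <- ifelse(zm <= cap, r_cap,
              prof$end_radius +
                (prof$shaft_radius - prof$end_radius) * t_ramp)
  pmax(r, 0)
}

bone_undulation <- function(z, theta, prof) {
  und <- prof$undulation
  if (is.null(und) || prof$undulation_amplitude <= 0) return(0 * z)
  s <- 0
  for (k in 1:3)
    s <- s + und$w[k] * cos(2 * pi * und$k_z[k] * z / prof$length +
                              und$phase_z[k]) *
      cos(und$k_t[k] * theta + und$phase_t[k])
  prof$undulation_amplitude * s
}

#' Fragment a synthetic bone with known ground truth
#'
#' Emulates blunt-force fragmentation of a long bone followed by scatter:
#' the cortical surface (outer plus endosteal shaft canal) is densely
#' sampled, partitioned by `n_fragments - 1` seeded near-transverse cut
#' planes through the shaft, and annular fracture-face points are synthesised
#' on each cut. The fracture relief is displacement along the cut normal:
#' a fine-scale bimodal (checkerboard) micro-asperity component
#' (`relief_hf_share` of the variance; it is what the roughness operator
#' responds to at a 2 mm kernel) plus a smooth band-limited field
#' (wavelengths `relief_wl`, the large-scale shape of the break), with total
#' RMS equal to `fracture_amplitude`. Cortical points carry only
#' `cortical_noise`. The two fragments meeting at a cut receive the *same*
#' face sample points (break surfaces conform), which is what makes ICP
#' mating exact. Every fragment is then moved by a seeded random rigid
#' scatter pose, which is recorded as ground truth. The intact reference
#' cloud is an independent, denser draw of the same surfaces, emulating the
#' separately scanned pre-fragmentation model.
#'
#' @param bone a mesh from [make_long_bone()] (its `metadata$profile` is
#'   required)
#' @param n_fragments integer >= 2; `NULL` (default) draws a count matching
#'   reported laboratory fragmentation statistics (mean 28.7, SD 7.8,
#'   observed range 20-43 per bone)
#' @param seed integer seed
#' @param fracture_amplitude RMS relief of fracture faces, mm (default 1.5:
#'   comfortably above the 1.0 segmentation threshold)
#' @param loss_fraction fraction of interior fragments deleted, emulating
#'   field loss of intermediate elements (default 0)
#' @param n_surface_points cortical sample size over the whole bone
#' @param face_spacing fracture-face grid spacing, mm
#' @param cortical_noise per-point cortical jitter amplitude, mm
#' @param scatter_translation half-width of the scatter translation cube, mm
#' @param relief_hf_share variance fraction of the fine bimodal relief
#' @param relief_cell checkerboard cell size of the fine relief, mm
#' @param relief_wl wavelength range of the smooth relief component, mm
#' @param intact_points sample size of the independent intact reference
#' @return list with `fragments` (named list of scattered `point_cloud`s) and
#'   `truth` (a `ground_truth`: per-fragment `poses`, per-point `labels`
#'   (cortical/fracture), the `intact` sampled surface in the bone frame,
#'   per-cut face points, per-fragment cut ids, lost fragment ids, params)
#' @export
fracture <- function(bone, n_fragments = NULL, seed,
                     fracture_amplitude = 1.5, loss_fraction = 0,
                     n_surface_points = 60000, face_spacing = 0.55,
                     cortical_noise = 0.05, scatter_translation = 100,
                     relief_hf_share = 0.09, relief_cell = 0.5,
                     relief_wl = c(30, 60), intact_points = 120000) {
  stopifnot(inherits(bone, "triangle_mesh"))
  prof <- bone$metadata$profile
  if (is.null(prof))
    stop("fracture() needs a generator bone with metadata$profile ",
         "(see make_long_bone)")
  if (!is.null(n_fragments) && n_fragments < 2) stop("n_fragments must be >= 2")
  if (loss_fraction < 0 || loss_fraction >= 1)
    stop("loss_fraction must be in [0, 1)")
  if (missing(seed)) stop("an explicit `seed` is required")
  L <- prof$length
  th <- prof$cortical_thickness
  r_in_shaft <- prof$shaft_radius - th
  if (r_in_shaft <= 0) stop("cortical_thickness >= shaft_radius")
  with_seed(seed, {
    if (is.null(n_fragments))
      n_fragments <- max(20L, min(43L, as.integer(round(rnorm(1, 28.7, 7.8)))))
    # --- cortical sampling: outer surface (mesh) + endosteal shaft canal
    areas <- triangle_areas(bone)
    zlo <- 0.15 * L
    zhi <- 0.85 * L
    a_outer <- sum(areas)
    a_inner <- 2 * pi * r_in_shaft * (zhi - zlo)
    sample_cortical <- function(n_total) {
      n_outer <- round(n_total * a_outer / (a_outer + a_inner))
      n_inner <- n_total - n_outer
      p_out <- sample_on_mesh(bone, areas, n_outer)
      z_in <- runif(n_inner, zlo, zhi)
      t_in <- runif(n_inner, 0, 2 * pi)
      p_in <- cbind(r_in_shaft * cos(t_in), r_in_shaft * sin(t_in), z_in)
      pts <- rbind(p_out, p_in)
      # per-point cortical jitter along the (radial) surface direction
      if (cortical_noise > 0) {
        rho <- sqrt(pts[, 1]^2 + pts[, 2]^2)
        ok <- rho > 1e-9
        jit <- runif(nrow(pts), -cortical_noise, cortical_noise)
        pts[ok, 1:2] <- pts[ok, 1:2] * (1 + jit[ok] / rho[ok])
        pts[!ok, 3] <- pts[!ok, 3] + jit[!ok]
      }
      pts
    }
    cortical <- sample_cortical(n_surface_points)
    # independent, denser draw: the intact reference model is acquired
    # separately from the fragments, as with a pre-fragmentation CT scan
    intact <- point_cloud(sample_cortical(intact_points),
                          metadata = list(surface = "cortical (outer + endosteal)"))
    # --- cut planes through the shaft
    n_cuts <- n_fragments - 1L
    cut_lo <- 0.16 * L
    cut_hi <- 0.84 * L
    dz <- (cut_hi - cut_lo) / n_cuts
    z_cut <- sort(cut_lo + (seq_len(n_cuts) - 0.5 + runif(n_cuts, -0.35, 0.35)) * dz)
    z_cut <- pmin(cut_hi, pmax(cut_lo, z_cut))
    max_tilt <- min(8, atan(0.35 * dz / prof$shaft_radius) * 180 / pi)
    tilt <- runif(n_cuts, 0, max_tilt) * pi / 180
    azim <- runif(n_cuts, 0, 2 * pi)
    normals <- cbind(sin(tilt) * cos(azim), sin(tilt) * sin(azim), cos(tilt))
    centres <- cbind(0, 0, z_cut)
    # --- partition cortical points into fragments
    side_count <- rep(0L, nrow(cortical))
    for (i in seq_len(n_cuts)) {
      s <- (cortical[, 1] - centres[i, 1]) * normals[i, 1] +
           (cortical[, 2] - centres[i, 2]) * normals[i, 2] +
           (cortical[, 3] - centres[i, 3]) * normals[i, 3]
      side_count <- side_count + as.integer(s > 0)
    }
    frag_of <- side_count + 1L
    # --- fracture faces: annular jittered grids, conforming relief
    faces <- vector("list", n_cuts)
    for (i in seq_len(n_cuts)) {
      nrm <- normals[i, ]
      u <- c(-nrm[2], nrm[1], 0)
      u <- u / sqrt(sum(u^2))
      v <- c(nrm[2] * u[3] - nrm[3] * u[2],
             nrm[3] * u[1] - nrm[1] * u[3],
             nrm[1] * u[2] - nrm[2] * u[1])
      g <- seq(-prof$shaft_radius - 1, prof$shaft_radius + 1, by = face_spacing)
      gg <- expand.grid(us = g, vs = g)
      gg$us <- gg$us + runif(nrow(gg), -0.25, 0.25) * face_spacing
      gg$vs <- gg$vs + runif(nrow(gg), -0.25, 0.25) * face_spacing
      p <- centres[rep(i, nrow(gg)), , drop = FALSE] +
        outer(gg$us, u) + outer(gg$vs, v)
      rho <- sqrt(p[, 1]^2 + p[, 2]^2)
      r_out_here <- bone_radius_profile(p[, 3], prof)
      keep <- rho <= r_out_here & rho >= r_in_shaft
      p <- p[keep, , drop = FALSE]
      gg <- gg[keep, , drop = FALSE]
      relief <- face_relief(gg$us, gg$vs, fracture_amplitude,
                            hf_share = relief_hf_share, cell = relief_cell,
                            wl_lo = relief_wl[1], wl_hi = relief_wl[2])
      faces[[i]] <- p + outer(relief, nrm)
    }
    # --- assemble fragments: cortical partition + bounding cut faces
    frag_cuts <- lapply(seq_len(n_fragments), function(k) {
      cuts <- integer(0)
      if (k > 1) cuts <- c(cuts, k - 1L)
      if (k <= n_cuts) cuts <- c(cuts, k)
      cuts
    })
    ids <- sprintf("frag%02d", seq_len(n_fragments))
    fragments <- list()
    labels <- list()
    poses <- list()
    for (k in seq_len(n_fragments)) {
      pts <- cortical[frag_of == k, , drop = FALSE]
      lab <- rep("cortical", nrow(pts))
      for (ci in frag_cuts[[k]]) {
        pts <- rbind(pts, faces[[ci]])
        lab <- c(lab, rep("fracture", nrow(faces[[ci]])))
      }
      pose_seed <- sample.int(2^30, 1)
      pose <- random_rigid_transform(pose_seed,
                                     max_translation = scatter_translation)
      scattered <- rt_apply(pose, pts)
      fragments[[ids[k]]] <- point_cloud(
        scattered, metadata = list(fragment_id = ids[k]))
      labels[[ids[k]]] <- lab
      poses[[ids[k]]] <- pose
    }
    # --- field loss of interior fragments
    lost <- character(0)
    if (loss_fraction > 0 && n_fragments > 2) {
      interior <- ids[2:(n_fragments - 1)]
      n_lost <- min(length(interior),
                    round(loss_fraction * (n_fragments - 2)))
      if (n_lost > 0) {
        lost <- sort(sample(interior, n_lost))
        fragments[lost] <- NULL
      }
    }
    truth <- structure(list(
      poses = poses, labels = labels, intact = intact,
      faces = faces, frag_cuts = stats::setNames(frag_cuts, ids),
      cut_centres = centres, cut_normals = normals,
      fragment_ids = ids, lost = lost,
      params = list(n_fragments = n_fragments,
                    fracture_amplitude = fracture_amplitude,
                    loss_fraction = loss_fraction,
                    cortical_noise = cortical_noise,
                    face_spacing = face_spacing, seed = seed,
                    profile = prof)), class = "ground_truth")
    list(fragments = fragments, truth = truth)
  })
}

# Fracture relief at in-plane coordinates (us, vs): bimodal checkerboard
# micro-asperities plus a smooth band-limited field, total RMS = amplitude.
# `hf_share` is the variance fraction carried by the checkerboard.
face_relief <- function(us, vs, amplitude, hf_share = 0.09, cell = 0.5,
                        wl_lo = 30, wl_hi = 60) {
  if (amplitude <= 0) return(0 * us)
  a_hf <- sqrt(hf_share) * amplitude
  a_sm <- sqrt(1 - hf_share) * amplitude
  sign_hf <- ifelse((floor(us / cell) + floor(vs / cell)) %% 2 == 0, 1, -1)
  n_waves <- 12L
  wl <- runif(n_waves, wl_lo, wl_hi)
  dir <- runif(n_waves, 0, 2 * pi)
  ph <- runif(n_waves, 0, 2 * pi)
  sm <- 0
  for (w in seq_len(n_waves))
    sm <- sm + cos(2 * pi / wl[w] * (us * cos(dir[w]) + vs * sin(dir[w])) +
                     ph[w])
  sm <- sm / sqrt(n_waves / 2)  # unit RMS for a sum of random cosines
  a_hf * sign_hf + a_sm * sm
}

#' Operator stand-in: build a match plan from ground truth
#'
#' Chains retained fragments in axial order, pairing consecutive fragments
#' that share a cut plane; for each pair, `n_correspondences` well-spread
#' points of the shared fracture face are expressed in each fragment's
#' scattered frame — the synthetic analogue of the operator clicking four
#' matching points on two fracture surfaces. Fragments separated by a lost
#' intermediate fragment share no face and are not paired.
#'
#' @param frag_set the list returned by [fracture()]
#' @param n_correspondences points per pair (>= 3, default 4)
#' @param seed integer seed (point selection)
#' @return a `match_plan`
#' @export
make_match_plan <- function(frag_set, n_correspondences = 4, seed = 1) {
  truth <- frag_set$truth
  present <- names(frag_set$fragments)
  ids <- truth$fragment_ids[truth$fragment_ids %in% present]
  steps <- list()
  with_seed(seed, {
    for (k in seq_along(ids)[-1]) {
      ref <- ids[k - 1]
      mov <- ids[k]
      shared <- intersect(truth$frag_cuts[[ref]], truth$frag_cuts[[mov]])
      if (length(shared) == 0) next
      fp <- truth$faces[[shared[1]]]
      # spread picks: order face points by azimuth, take quantile positions
      ang <- atan2(fp[, 2], fp[, 1])
      ord <- order(ang)
      pick <- ord[round(seq(1, length(ord),
                            length.out = n_correspondences + 1))[-1]]
      p_bone <- fp[pick, , drop = FALSE]
      steps[[length(steps) + 1]] <- list(
        ref = ref, mov = mov,
        ref_points = rt_apply(truth$poses[[ref]], p_bone),
        mov_points = rt_apply(truth$poses[[mov]], p_bone))
    }
  })
  match_plan(steps)
}

#' True relative pose of a fragment in the assembly frame
#'
#' The assembly frame is the scattered frame of `anchor_id` (the first
#' reference fragment). For fragment `id`, the true pose that [reassemble()]
#' should recover is `S_anchor o S_id^-1` where `S` are scatter poses.
#'
#' @param truth a `ground_truth`
#' @param id,anchor_id fragment ids
#' @return a `rigid_transform`
#' @export
true_relative_pose <- function(truth, id, anchor_id) {
  rt_compose(truth$poses[[anchor_id]], rt_invert(truth$poses[[id]]))
}

#' Pose error between a recovered and a true transform
#'
#' Rotation error is the geodesic angle of `R_rec R_true^T` (degrees);
#' translation error is the displacement (mm) of `at` (typically the fragment
#' centroid) under the discrepancy transform — origin-independent.
#'
#' @param recovered,truth `rigid_transform`s
#' @param at point(s) at which to evaluate displacement (n x 3)
#' @return list `angle_deg`, `translation_mm` (mean displacement at `at`)
#' @export
pose_error <- function(recovered, truth, at = matrix(0, 1, 3)) {
  disc <- rt_compose(recovered, rt_invert(truth))
  at <- matrix(at, ncol = 3)
  moved <- rt_apply(truth, at)          # where the fragment actually sits
  d <- rt_apply(disc, moved) - moved
  list(angle_deg = rt_angle_deg(disc),
       translation_mm = mean(sqrt(rowSums(d^2))))
}

#' Voxelize meshes into a synthetic CT volume
#'
#' Solid-interior voxelization by vertical ray parity against the closed
#' surface: interior voxels are set to `hu_bone` with seeded multiplicative
#' noise (3% half-width), an optional soft-tissue shell of the given
#' thickness surrounds the bone at `hu_soft`, and everything else is
#' `hu_air`. A shell thickness > 0 emulates fleshed remains, whose
#' segmentation behaves differently from cleaned bone.
#'
#' @param x a watertight `triangle_mesh` or list of meshes
#' @param spacing isotropic voxel size, mm
#' @param hu_bone,hu_soft,hu_air attenuation values (HU)
#' @param soft_shell soft-tissue shell thickness, mm (0 = none)
#' @param seed integer seed for the attenuation noise
#' @param noise_frac half-width of the multiplicative bone noise (0.03 = 3%)
#' @return a `ct_volume`; provenance records parameters and any thin-feature
#'   warning
#' @export
voxelize <- function(x, spacing, hu_bone = 1500, hu_soft = 40,
                     hu_air = -1000, soft_shell = 0, seed = 1,
                     noise_frac = 0.03) {
  if (spacing <= 0) stop("spacing must be positive")
  meshes <- if (inherits(x, "triangle_mesh")) list(x) else x
  stopifnot(all(vapply(meshes, inherits, logical(1), "triangle_mesh")))
  allv <- do.call(rbind, lapply(meshes, function(m) m$vertices))
  margin <- soft_shell + 2 * spacing
  lo <- apply(allv, 2, min) - margin
  hi <- apply(allv, 2, max) + margin
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  origin <- lo
  inside <- array(FALSE, dim = dims)
  for (m in meshes)
    inside <- inside | voxelize_one(m, dims, origin, spacing)
  warn <- NULL
  thin <- vapply(meshes, function(m) {
    p <- m$metadata$profile
    if (!is.null(p)) p$cortical_thickness else Inf
  }, numeric(1))
  if (spacing > min(thin))
    warn <- sprintf("voxel spacing %g mm exceeds thinnest feature %g mm",
                    spacing, min(thin))
  vox <- array(hu_air, dim = dims)
  if (soft_shell > 0) {
    shell <- dilate_mask(inside, ceiling(soft_shell / spacing)) & !inside
    vox[shell] <- hu_soft
  }
  nb <- sum(inside)
  vox[inside] <- with_seed(seed,
                           hu_bone * (1 + runif(nb, -noise_frac, noise_frac)))
  ct_volume(vox, spacing = rep(spacing, 3), origin = origin,
            provenance = list(generator = "voxelize", hu_bone = hu_bone,
                              hu_soft = hu_soft, hu_air = hu_air,
                              soft_shell = soft_shell, seed = seed,
                              warning = warn))
}

# parity fill along z columns for one closed mesh
voxelize_one <- function(mesh, dims, origin, spacing) {
  v <- mesh$vertices
  f <- mesh$faces
  inside <- array(FALSE, dim = dims)
  nxy <- dims[1] * dims[2]
  # z coordinates of voxel centres
  zs <- origin[3] + (seq_len(dims[3]) - 1) * spacing
  # per-column crossing lists, accumulated triangle by triangle
  crossings <- vector("list", nxy)
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  for (t_i in seq_len(nrow(f))) {
    a <- p1[t_i, ]; b <- p2[t_i, ]; cc <- p3[t_i, ]
    ilo <- max(1L, as.integer(floor((min(a[1], b[1], cc[1]) - origin[1]) /
                                      spacing)) + 1L)
    ihi <- min(dims[1], as.integer(ceiling((max(a[1], b[1], cc[1]) -
                                              origin[1]) / spacing)) + 1L)
    jlo <- max(1L, as.integer(floor((min(a[2], b[2], cc[2]) - origin[2]) /
                                      spacing)) + 1L)
    jhi <- min(dims[2], as.integer(ceiling((max(a[2], b[2], cc[2]) -
                                              origin[2]) / spacing)) + 1L)
    if (ilo > ihi || jlo > jhi) next
    cols <- expand.grid(i = ilo:ihi, j = jlo:jhi)
    px <- origin[1] + (cols$i - 1) * spacing
    py <- origin[2] + (cols$j - 1) * spacing
    # 2D barycentric in the xy projection
    d <- (b[2] - cc[2]) * (a[1] - cc[1]) + (cc[1] - b[1]) * (a[2] - cc[2])
    if (abs(d) < 1e-12) next
    w1 <- ((b[2] - cc[2]) * (px - cc[1]) + (cc[1] - b[1]) * (py - cc[2])) / d
    w2 <- ((cc[2] - a[2]) * (px - cc[1]) + (a[1] - cc[1]) * (py - cc[2])) / d
    w3 <- 1 - w1 - w2
    hit <- w1 >= 0 & w2 >= 0 & w3 >= 0
    if (!any(hit)) next
    zhit <- w1[hit] * a[3] + w2[hit] * b[3] + w3[hit] * cc[3]
    keys <- (cols$j[hit] - 1L) * dims[1] + cols$i[hit]
    for (h in seq_along(keys))
      crossings[[keys[h]]] <- c(crossings[[keys[h]]], zhit[h])
  }
  for (key in which(!vapply(crossings, is.null, logical(1)))) {
    zc <- sort(crossings[[key]])
    if (length(zc) < 2) next
    i <- ((key - 1L) %% dims[1]) + 1L
    j <- ((key - 1L) %/% dims[1]) + 1L
    # pair up entry/exit crossings
    for (p_i in seq(1, 2 * floor(length(zc) / 2), by = 2)) {
      sel <- zs >= zc[p_i] & zs <= zc[p_i + 1]
      if (any(sel)) inside[i, j, sel] <- TRUE
    }
  }
  inside
}

dilate_mask <- function(mask, passes) {
  d <- dim(mask)
  for (p in seq_len(passes)) {
    grown <- mask
    grown[-1, , ] <- grown[-1, , ] | mask[-d[1], , ]
    grown[-d[1], , ] <- grown[-d[1], , ] | mask[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | mask[, -d[2], ]
    grown[, -d[2], ] <- grown[, -d[2], ] | mask[, -1, ]
    grown[, , -1] <- grown[, , -1] | mask[, , -d[3]]
    grown[, , -d[3]] <- grown[, , -d[3]] | mask[, , -1]
    mask <- grown
  }
  mask
}
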