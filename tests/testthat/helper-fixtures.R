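# Shared fixtures (built in code, cached per session) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

fix_bone <- function() {
  if (is.null(.fixtures$bone)) .fixtures$bone <- make_long_bone(seed = 3)
  .fixtures$bone
}

# small fragmented bone: 4 fragments, default relief
fix_frags <- function() {
  if (is.null(.fixtures$frags))
    .fixtures$frags <- fracture(fix_bone(), n_fragments = 4, seed = 11)
  .fixtures$frags
}

make_cube_mesh <- function(side = 1) {
  v <- as.matrix(expand.grid(x = c(0, side), y = c(0, side),
                             z = c(0, side)))
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z = 0
    c(5, 6, 8), c(5, 8, 7),   # z = side
    c(1, 2, 6), c(1, 6, 5),   # y = 0
    c(3, 7, 8), c(3, 8, 4),   # y = side
    c(1, 5, 7), c(1, 7, 3),   # x = 0
    c(2, 4, 8), c(2, 8, 6))   # x = side
  triangle_mesh(v, f)
}

make_sphere_mesh <- function(r = 10, n_th = 48, n_ph = 96) {
  th <- seq(0, pi, length.out = n_th + 1)[-c(1, n_th + 1)]
  ph <- seq(0, 2 * pi, length.out = n_ph + 1)[-(n_ph + 1)]
  g <- expand.grid(ph = ph, th = th)
  v <- r * cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))
  v <- rbind(v, c(0, 0, r), c(0, 0, -r))
  nr <- n_th - 1
  idx <- function(i, j) (i - 1) * n_ph + ((j - 1) %% n_ph) + 1
  f <- list()
  for (i in seq_len(nr - 1)) {
    j <- seq_len(n_ph)
    f[[i]] <- rbind(cbind(idx(i, j), idx(i, j + 1), idx(i + 1, j + 1)),
                    cbind(idx(i, j), idx(i + 1, j + 1), idx(i + 1, j)))
  }
  top <- nrow(v) - 1
  bot <- nrow(v)
  j <- seq_len(n_ph)
  f[[nr]] <- cbind(idx(1, j + 1), idx(1, j), top)
  f[[nr + 1]] <- cbind(idx(nr, j), idx(nr, j + 1), bot)
  triangle_mesh(v, do.call(rbind, f))
}

# O(N^2) nearest-neighbour oracle
brute_nearest <- function(query, reference) {
  apply(query, 1, function(q)
    sqrt(min(colSums((t(reference) - q)^2))))
}

# explicit LS-plane roughness oracle (neighbours within radius, query excluded)
oracle_roughness <- function(pts, radius) {
  n <- nrow(pts)
  out <- rep(NA_real_, n)
  d2 <- as.matrix(dist(pts))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] <= radius^2)
    nb <- setdiff(nb, i)
    if (length(nb) < 3) next
    q <- pts[nb, , drop = FALSE]
    cen <- colMeans(q)
    cc <- crossprod(sweep(q, 2, cen))
    ev <- eigen(cc, symmetric = TRUE)
    if (ev$values[2] <= 1e-12 * sum(ev$values)) next
    nrm <- ev$vectors[, 3]
    out[i] <- abs(sum(nrm * (pts[i, ] - cen)))
  }
  out
}

# single-seed flood-fill oracle for region growing (26-connectivity)
oracle_flood <- function(vol, seed, lower) {
  d <- dim(vol)
  lab <- array(FALSE, dim = d)
  stack <- list(seed)
  lab[seed[1], seed[2], seed[3]] <- TRUE
  while (length(stack) > 0) {
    v <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      w <- v + c(dx, dy, dz)
      if (any(w < 1) || any(w > d)) next
      if (lab[w[1], w[2], w[3]] || vol[w[1], w[2], w[3]] < lower) next
      lab[w[1], w[2], w[3]] <- TRUE
      stack[[length(stack) + 1]] <- w
    }
  }
  lab
}

# pose errors of a reassembly result against generator truth
pose_errors <- function(res, frag_set, plan) {
  anchor <- plan$steps[[1]]$ref
  ids <- setdiff(names(res$poses), anchor)
  t(vapply(ids, function(id) {
    tp <- true_relative_pose(frag_set$truth, id, anchor)
    cen <- colMeans(frag_set$fragments[[id]]$points)
    e <- pose_error(res$poses[[id]], tp, at = matrix(cen, 1))
    c(angle = e$angle_deg, trans = e$translation_mm)
  }, numeric(2)))
}

# small rigid perturbation (axis-angle), for ICP basin-of-attraction tests
small_rigid <- function(seed, max_angle_deg = 5, max_trans = 2) {
  with_seed(seed, {
    ax <- rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    ang <- runif(1, 0.2, max_angle_deg) * pi / 180
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, byrow = TRUE)
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
    rigid_transform(R, runif(3, -max_trans, max_trans))
  })
}
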