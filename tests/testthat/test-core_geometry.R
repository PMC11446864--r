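# Core geometric types, mesh/cloud I/O, subsampling, rigid transforms and
# nearest-neighbour queries.

test_that("STL reading handles both dialects and minimal input", {
  # minimal one-triangle ASCII STL
  f <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid tri", "facet normal 0 0 1", "outer loop",
               "vertex 0 0 0", "vertex 1 0 0", "vertex 0 1 0",
               "endloop", "endfacet", "endsolid tri"), f)
  m <- load_mesh(f)
  expect_equal(nrow(m$vertices), 3)
  expect_equal(nrow(m$faces), 1)

  # the same unit cube in binary and ASCII gives identical vertex sets
  cube <- make_cube_mesh()
  fb <- withr::local_tempfile(fileext = ".stl")
  fa <- withr::local_tempfile(fileext = ".stl")
  save_mesh(cube, fb)
  save_mesh(cube, fa, ascii = TRUE)
  mb <- load_mesh(fb)
  ma <- load_mesh(fa)
  sort_rows <- function(v) v[do.call(order, as.data.frame(v)), ]
  expect_equal(sort_rows(mb$vertices), sort_rows(ma$vertices),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(nrow(mb$vertices), 8)
  expect_equal(nrow(mb$faces), 12)
})

test_that("STL round-trip is lossless to the 32-bit float floor", {
  bone <- fix_bone()
  f <- withr::local_tempfile(fileext = ".stl")
  save_mesh(bone, f)
  back <- load_mesh(f)
  expect_equal(nrow(back$faces), nrow(bone$faces))
  # same vertex multiset within float32 rounding of mm-scale coordinates
  nn <- nearest_distances(point_cloud(back$vertices),
                          point_cloud(bone$vertices))
  expect_lt(max(nn), 1e-4)
})

test_that("STL error paths name the problem", {
  expect_error(load_mesh("no/such/file.stl"), "does not exist")
  cube <- make_cube_mesh()
  f <- withr::local_tempfile(fileext = ".stl")
  save_mesh(cube, f)
  raw <- readBin(f, "raw", n = file.info(f)$size)
  writeBin(raw[1:150], f)  # truncate mid-body
  expect_error(load_mesh(f), "byte")
  expect_error(save_mesh(triangle_mesh(matrix(numeric(0), ncol = 3),
                                       matrix(integer(0), ncol = 3)),
                         withr::local_tempfile(fileext = ".stl")),
               "empty")
})

test_that("PLY preserves per-vertex scalars exactly", {
  cl <- point_cloud(matrix(runif(90), ncol = 3),
                    scalar = runif(30, 0, 3))
  f <- withr::local_tempfile(fileext = ".ply")
  save_cloud(cl, f)
  back <- load_cloud(f)
  expect_equal(back$points, cl$points, ignore_attr = TRUE)
  expect_identical(back$scalar, cl$scalar)
})

test_that("mesh and cloud validators reject malformed input", {
  expect_error(triangle_mesh(matrix(0, 3, 3), rbind(c(1, 1, 2))),
               "degenerate")
  expect_error(triangle_mesh(matrix(0, 3, 3), rbind(c(1, 2, 4))),
               "out of range")
  expect_error(point_cloud(matrix(1, 4, 3), scalar = 1:3), "length")
  expect_error(point_cloud(matrix(c(1, NA, 1), 1, 3)), "finite")
})

test_that("subsample returns exactly n points, reproducibly, in both modes", {
  cube <- make_cube_mesh()
  for (n in c(1, 2, 1000)) {
    for (mode in c("random_area_weighted", "homogeneous")) {
      cl <- subsample(cube, n, seed = 7, mode = mode)
      expect_equal(n_points(cl), n)
    }
  }
  a <- subsample(cube, 500, seed = 42)
  b <- subsample(cube, 500, seed = 42)
  expect_identical(a$points, b$points)
  expect_error(subsample(cube, 100), "seed")
  expect_error(subsample(cube, 0, seed = 1), ">= 1")
})

test_that("subsampled points lie on the surface and follow triangle areas", {
  # planar containment: two-triangle unit square at z = 0
  sq <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                      rbind(c(1, 2, 3), c(1, 3, 4)))
  cl <- subsample(sq, 10, seed = 1)
  expect_true(all(cl$points[, 1] >= 0 & cl$points[, 1] <= 1))
  expect_true(all(cl$points[, 2] >= 0 & cl$points[, 2] <= 1))
  expect_true(all(cl$points[, 3] == 0))

  # area weighting: 9:1 triangles, count within 3 binomial sigma
  two <- triangle_mesh(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0),
                             c(10, 0, 0), c(11, 0, 0), c(10, 1, 0)),
                       rbind(c(1, 2, 3), c(4, 5, 6)))
  cl <- subsample(two, 10000, seed = 5)
  n_large <- sum(cl$points[, 1] < 5)
  expect_lt(abs(n_large - 9000), 3 * sqrt(10000 * 0.9 * 0.1))
})

test_that("homogeneous subsampling spreads points more evenly than random", {
  bone <- fix_bone()
  n <- 3000
  r_rand <- subsample(bone, n, seed = 2, mode = "random_area_weighted")
  r_homo <- subsample(bone, n, seed = 2, mode = "homogeneous")
  min_gap <- function(cl) {
    # inter-point spacing proxy: each point against the other half
    half <- seq_len(floor(n / 2))
    a <- point_cloud(cl$points[half, ])
    b <- point_cloud(cl$points[-half, ])
    median(as.numeric(nearest_distances(a, b)))
  }
  expect_gt(min_gap(r_homo), min_gap(r_rand))
  expect_identical(r_homo$metadata$subsample_mode, "homogeneous")
})

test_that("rigid transforms compose, invert and preserve distances", {
  expect_equal(rt_apply(rt_identity(), matrix(1:6, 2)), matrix(1:6, 2))
  tr <- rigid_transform(diag(3), c(1, 2, 3))
  expect_equal(rt_apply(tr, matrix(0, 1, 3)), matrix(c(1, 2, 3), 1))

  pts <- matrix(rnorm(60), ncol = 3)
  for (s in 1:5) {
    t1 <- random_rigid_transform(s)
    t2 <- random_rigid_transform(s + 100)
    via_compose <- rt_apply(rt_compose(t2, t1), pts)
    sequential <- rt_apply(t2, rt_apply(t1, pts))
    expect_lt(max(abs(via_compose - sequential)), 1e-9)
    # inversion
    expect_lt(max(abs(rt_apply(rt_invert(t1), rt_apply(t1, pts)) - pts)),
              1e-9)
    # isometry
    d0 <- dist(pts)
    d1 <- dist(rt_apply(t1, pts))
    expect_lt(max(abs(d0 - d1)), 1e-9)
  }
  expect_error(rigid_transform(diag(c(1, 1, -1))), "determinant")
  expect_error(rigid_transform(matrix(rnorm(9), 3)), "orthonormal")
})

test_that("nearest_distances matches the brute-force oracle", {
  cl <- point_cloud(matrix(runif(300), ncol = 3))
  expect_equal(as.numeric(nearest_distances(cl, cl)), rep(0, 100))

  with_seed(99, {
    q <- matrix(runif(300, 0, 10), ncol = 3)
    r <- matrix(runif(1500, 0, 10), ncol = 3)
  })
  got <- as.numeric(nearest_distances(point_cloud(q), point_cloud(r)))
  expect_equal(got, brute_nearest(q, r), tolerance = 1e-12)

  # point above a dense plane
  plane <- point_cloud(cbind(as.matrix(expand.grid(seq(-1, 1, 0.05),
                                                   seq(-1, 1, 0.05))), 0))
  d <- nearest_distances(point_cloud(matrix(c(0, 0, 2), 1)), plane)
  expect_equal(as.numeric(d), 2, tolerance = 1e-9)

  expect_error(nearest_distances(cl, point_cloud(matrix(numeric(0),
                                                        ncol = 3))),
               "empty")
})

test_that("mesh measures are correct on the unit cube", {
  cube <- make_cube_mesh()
  expect_true(mesh_is_watertight(cube))
  expect_equal(mesh_area(cube), 6)
  expect_equal(mesh_volume(cube), 1)
})
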