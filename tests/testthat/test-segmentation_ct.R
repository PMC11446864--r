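# CT volumes, NRRD I/O, seeded region growing, surface extraction and the
# fragment length filter.

test_that("NRRD volumes round-trip values, spacing and both encodings", {
  with_seed(4, v <- array(round(runif(64^3, -1000, 2000)), dim = c(64, 64, 64)))
  vol <- ct_volume(v, spacing = c(0.5, 0.5, 0.5),
                   provenance = list(slice_thickness_mm = 0.625,
                                     slice_interval_mm = 0.315))
  expect_equal(vol$provenance$slice_thickness_mm, 0.625)

  for (enc in c("raw", "text")) {
    f <- withr::local_tempfile(fileext = ".nrrd")
    save_volume(vol, f, encoding = enc)
    back <- load_volume(f)
    expect_equal(back$spacing, c(0.5, 0.5, 0.5))
    expect_equal(back$voxels, vol$voxels)
  }
  expect_error(ct_volume(v, spacing = c(0, 1, 1)), "positive")
})

test_that("region growing matches a flood-fill oracle and is competitive", {
  # uniform saturated volume: one seed labels everything
  vol <- ct_volume(array(500, dim = c(8, 8, 8)), spacing = rep(1, 3))
  mask <- region_grow(vol, rbind(c(1, 1, 1)), lower_hu = 300)
  expect_true(all(mask$labels == 1))

  # two blobs separated by background: one seed grows only its blob
  v <- array(0, dim = c(20, 20, 20))
  v[3:8, 3:8, 3:8] <- 1000
  v[14:18, 14:18, 14:18] <- 1000
  vol <- ct_volume(v, spacing = rep(1, 3))
  mask <- region_grow(vol, rbind(c(4, 4, 4)), lower_hu = 300)
  oracle <- oracle_flood(v, c(4, 4, 4), 300)
  expect_identical(mask$labels == 1, oracle)
  expect_equal(sum(mask$labels == 1), 6^3)

  # two touching blocks, one seed each: labels partition the bone voxels
  v <- array(0, dim = c(20, 10, 10))
  v[2:18, 3:8, 3:8] <- 800
  vol <- ct_volume(v, spacing = rep(1, 3))
  mask <- region_grow(vol, rbind(c(2, 5, 5), c(18, 5, 5)), lower_hu = 300)
  expect_true(all((mask$labels > 0) == (v >= 300)))
  expect_true(all(sort(unique(as.vector(mask$labels))) == 0:2))
  # competitive growth splits at the midplane; equidistant ties go low
  expect_true(all(mask$labels[2:9, 3:8, 3:8] == 1))
  expect_true(all(mask$labels[12:18, 3:8, 3:8] == 2))

  # seed order permutation only permutes labels, except on contested
  # equal-distance voxels (the documented lower-label tie rule)
  mask_b <- region_grow(vol, rbind(c(18, 5, 5), c(2, 5, 5)), lower_hu = 300)
  expect_true(all(mask_b$labels[2:9, 3:8, 3:8] == 2))
  expect_true(all(mask_b$labels[12:18, 3:8, 3:8] == 1))

  expect_error(region_grow(vol, rbind(c(1, 1, 1)), lower_hu = 300),
               "below threshold")
})

test_that("extract_surface produces watertight, metrically accurate meshes", {
  # single interior voxel: closed surface enclosing ~ the voxel volume
  v <- array(0, dim = c(5, 5, 5))
  v[3, 3, 3] <- 1000
  vol <- ct_volume(v, spacing = rep(1, 3))
  mask <- region_grow(vol, rbind(c(3, 3, 3)), lower_hu = 300)
  m <- extract_surface(mask, 1, vol, smooth_passes = 0)
  expect_true(mesh_is_watertight(m))
  expect_lte(abs(mesh_volume(m) - 1), 0.5)
  expect_error(extract_surface(mask, 7, vol), "absent")

  # voxelized sphere r = 10 at 0.5 mm: area within 5% of 4 pi r^2
  sph <- make_sphere_mesh(r = 10)
  svol <- voxelize(sph, spacing = 0.5, seed = 1)
  seedv <- which(svol$voxels == max(svol$voxels), arr.ind = TRUE)[1, ]
  smask <- region_grow(svol, matrix(seedv, 1), lower_hu = 300)
  sm <- extract_surface(smask, 1, svol)
  expect_true(mesh_is_watertight(sm))
  expect_lt(abs(mesh_area(sm) / (4 * pi * 100) - 1), 0.05)

  # extracted surface hugs the generating surface (within a voxel diagonal)
  pts <- subsample(sm, 2000, seed = 3)
  ref <- subsample(sph, 20000, seed = 4)
  expect_lt(max(as.numeric(nearest_distances(pts, ref))), sqrt(3) * 0.5)
})

test_that("fragment length is principal-axis extent and drives retention", {
  box <- triangle_mesh(as.matrix(expand.grid(c(0, 30), c(0, 5), c(0, 5))),
                       make_cube_mesh()$faces)
  expect_equal(fragment_length(box), sqrt(30^2), tolerance = 1e-9)

  rot <- random_rigid_transform(8)
  box_r <- triangle_mesh(rt_apply(rot, box$vertices), box$faces)
  expect_equal(fragment_length(box_r), fragment_length(box),
               tolerance = 1e-6)

  short <- triangle_mesh(as.matrix(expand.grid(c(0, 15), c(0, 4), c(0, 4))),
                         make_cube_mesh()$faces)
  kept <- filter_by_length(list(a = box, b = short), min_length = 20)
  expect_identical(names(kept), "a")
  expect_equal(unname(attr(kept, "lengths")), c(30, 15), tolerance = 1e-9)
})
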