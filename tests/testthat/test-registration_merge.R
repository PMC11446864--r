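# Correspondence alignment, trimmed ICP, pairwise re-association and
# sequential whole-bone reassembly.

test_that("rigid_from_correspondences is exact on constructed pairs", {
  with_seed(1, ref <- matrix(runif(30, -50, 50), ncol = 3))
  ident <- rigid_from_correspondences(ref, ref)
  expect_lt(max(abs(ident$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(ident$translation)), 1e-9)

  for (s in 1:8) {
    tr <- random_rigid_transform(s, max_translation = 80)
    mov <- rt_apply(rt_invert(tr), ref)
    got <- rigid_from_correspondences(ref, mov)
    expect_lt(max(abs(got$rotation - tr$rotation)), 1e-9)
    expect_lt(max(abs(got$translation - tr$translation)), 1e-9)
  }
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(rigid_from_correspondences(line, line + 1), "collinear")
  expect_error(rigid_from_correspondences(ref[1:2, ], ref[1:2, ]), ">= 3")
})

test_that("noisy correspondence solution beats random perturbations", {
  with_seed(9, {
    ref <- matrix(runif(12, -20, 20), ncol = 3)
    tr <- random_rigid_transform(55)
    mov <- rt_apply(rt_invert(tr), ref) + matrix(rnorm(12, sd = 0.3), ncol = 3)
  })
  fit <- rigid_from_correspondences(ref, mov)
  rss <- function(t2) sum((rt_apply(t2, mov) - ref)^2)
  base <- rss(fit)
  with_seed(10, {
    worse <- replicate(500, {
      ang <- rnorm(1, sd = 0.02)
      ax <- c(0, 0, 1)
      R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
                  3, byrow = TRUE)
      rss(rt_compose(rigid_transform(R, rnorm(3, sd = 0.05)), fit))
    })
  })
  expect_true(all(base <= worse))
})

test_that("trimmed ICP converges on aligned clouds and recovers poses", {
  face <- point_cloud(fix_frags()$truth$faces[[1]])
  rec <- icp_refine(face, face)
  expect_lte(rec$iterations, 2)
  expect_lt(rec$final_rms, 1e-9)
  expect_true(rec$converged)

  # seeded 5 degree tilt + 3 mm translation
  ang <- 5 * pi / 180
  R <- matrix(c(1, 0, 0, 0, cos(ang), -sin(ang), 0, sin(ang), cos(ang)),
              3, byrow = TRUE)
  truth <- rigid_transform(R, c(2, -1, 2))
  mov <- apply_transform(face, rt_invert(truth))

  # identity init: ICP contracts the pose error substantially, but the
  # fine fracture relief leaves it short of exact lock (basin narrower than
  # the micro-asperity cell) — which is why the protocol always seeds ICP
  # with operator correspondence points first
  rec0 <- icp_refine(face, mov)
  e0 <- pose_error(rec0$transform, truth,
                   at = matrix(colMeans(mov$points), 1))
  expect_lt(e0$angle_deg, 1.5)
  expect_lt(e0$translation_mm, 1.5)

  # correspondence-seeded init (the protocol's flow): exact recovery
  pick <- round(seq(1, n_points(face), length.out = 4))
  seed_tr <- rigid_from_correspondences(face$points[pick, , drop = FALSE],
                                        mov$points[pick, , drop = FALSE])
  rec <- icp_refine(face, mov, init = seed_tr,
                    params = list(trim_keep_fraction = 0.2,
                                  max_corr_dist = 2))
  e <- pose_error(rec$transform, truth,
                  at = matrix(colMeans(mov$points), 1))
  expect_lt(e$angle_deg, 0.1)
  expect_lt(e$translation_mm, 0.05)
})

test_that("the trimmed ICP objective is non-increasing across iterations", {
  face <- fix_frags()$truth$faces[[2]]
  for (s in 1:20) {
    pert <- small_rigid(s)
    mov <- point_cloud(rt_apply(pert, face))
    rec <- icp_refine(point_cloud(face), mov,
                      params = list(trim_keep_fraction = 0.7))
    expect_true(all(diff(rec$rms_history) <= 1e-12))
  }
})

test_that("ICP reports diagnostics and fails loudly with no correspondences", {
  a <- point_cloud(matrix(runif(90), ncol = 3))
  b <- point_cloud(matrix(runif(90) + 500, ncol = 3))
  expect_error(icp_refine(a, b, params = list(max_corr_dist = 5)),
               "non-convergence")
  expect_error(icp_refine(a, b, params = list(trim_keep_fraction = 0)),
               "trim_keep_fraction")
})

test_that("reassociate_pair transfers the surface transform to the fragment", {
  fs <- fix_frags()
  ids <- names(fs$fragments)[1:2]
  unscattered <- lapply(ids, function(id)
    apply_transform(fs$fragments[[id]], rt_invert(fs$truth$poses[[id]])))
  surf <- lapply(unscattered, function(fr)
    segment_fracture(roughness(fr, 2), 0.2))
  shared <- fs$truth$faces[[1]][c(10, 80, 150, 220), ]

  # moving fragment already in place, identity correspondences
  out <- reassociate_pair(unscattered[[1]], unscattered[[2]],
                          surf[[1]], surf[[2]],
                          list(ref = shared, mov = shared),
                          params = list(trim_keep_fraction = 0.2,
                                        max_corr_dist = 2))
  expect_equal(n_points(out$merged),
               n_points(unscattered[[1]]) + n_points(unscattered[[2]]))
  expect_lt(rt_angle_deg(out$transform), 0.1)
  expect_lt(sqrt(sum(out$transform$translation^2)), 0.1)

  # half-bone pair: merged cloud sits on the intact surface
  two <- fracture(fix_bone(), n_fragments = 2, seed = 31)
  s2 <- lapply(two$fragments, function(fr)
    segment_fracture(roughness(fr, 2), 0.2))
  fp <- two$truth$faces[[1]][c(5, 60, 130, 200), ]
  corr <- list(ref = rt_apply(two$truth$poses[[1]], fp),
               mov = rt_apply(two$truth$poses[[2]], fp))
  out2 <- reassociate_pair(two$fragments[[1]], two$fragments[[2]],
                           s2[[1]], s2[[2]], corr,
                           params = list(trim_keep_fraction = 0.2,
                                         max_corr_dist = 2))
  cmp <- register_and_compare(out2$merged, two$truth$intact)
  expect_lt(cmp$metrics$rms_distance, 0.5)
})

test_that("match plans validate and round-trip through JSON", {
  fs <- fix_frags()
  plan <- make_match_plan(fs, seed = 5)
  expect_s3_class(plan, "match_plan")
  expect_length(plan$steps, 3)
  f <- withr::local_tempfile(fileext = ".json")
  save_match_plan(plan, f)
  back <- load_match_plan(f)
  for (k in seq_along(plan$steps)) {
    expect_identical(back$steps[[k]]$ref, plan$steps[[k]]$ref)
    expect_equal(back$steps[[k]]$ref_points, plan$steps[[k]]$ref_points,
                 ignore_attr = TRUE)
  }
  bad <- plan$steps
  bad[[1]]$mov_points <- cbind(1:4, 1:4, 1:4)
  expect_error(match_plan(bad), "collinear")
})

test_that("reassemble recovers all true poses and records failures", {
  fs <- fix_frags()
  plan <- make_match_plan(fs, seed = 5)
  params <- list(kernel_radius = 2, threshold = 0.2,
                 trim_keep_fraction = 0.2, max_corr_dist = 2)
  res <- reassemble(fs$fragments, plan, params)
  expect_equal(res$n_merged, 4)
  expect_equal(n_points(res$merged),
               sum(vapply(fs$fragments, n_points, numeric(1))))
  errs <- pose_errors(res, fs, plan)
  expect_lt(max(errs[, "angle"]), 0.5)
  expect_lt(max(errs[, "trans"]), 0.5)
  # pose chains: stored poses reproduce each step transform composition
  for (s in res$steps)
    expect_lt(max(abs(res$poses[[s$mov]]$rotation -
                        s$record$transform$rotation)), 1e-12)

  # empty plan: nothing moves, nothing merges
  empty <- reassemble(fs$fragments, match_plan(list()))
  expect_equal(empty$n_attempted, 0)

  # a step with garbage correspondences fails; earlier merges are unaffected
  junk <- plan
  junk$steps[[3]]$mov_points <- junk$steps[[3]]$mov_points + 500
  res_j <- reassemble(fs$fragments, junk, params)
  status <- vapply(res_j$steps, `[[`, character(1), "status")
  expect_identical(status[3], "failed")
  expect_identical(status[c(1, 2)], c("merged", "merged"))
  expect_equal(res_j$n_merged, 3)
})

test_that("reassembly is equivariant under a common rigid motion", {
  fs <- fix_frags()
  plan <- make_match_plan(fs, seed = 5)
  params <- list(kernel_radius = 2, threshold = 0.2,
                 trim_keep_fraction = 0.2, max_corr_dist = 2)
  res <- reassemble(fs$fragments, plan, params)

  g <- random_rigid_transform(123, max_translation = 40)
  frags_g <- lapply(fs$fragments, apply_transform, g)
  plan_g <- plan
  for (k in seq_along(plan_g$steps)) {
    plan_g$steps[[k]]$ref_points <- rt_apply(g, plan_g$steps[[k]]$ref_points)
    plan_g$steps[[k]]$mov_points <- rt_apply(g, plan_g$steps[[k]]$mov_points)
  }
  res_g <- reassemble(frags_g, plan_g, params)
  expect_lt(max(abs(res_g$merged$points - rt_apply(g, res$merged$points))),
            1e-6)
})
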