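# Evaluation battery: registration-based comparison, coverage, summary
# statistics and paired correlations on the six-femur benchmark table.

test_that("register_and_compare recovers displaced copies exactly", {
  with_seed(3, cl <- point_cloud(matrix(runif(6000, 0, 50), ncol = 3)))
  same <- register_and_compare(cl, cl)
  expect_equal(same$metrics$mean_distance, 0, tolerance = 1e-9)
  expect_equal(same$metrics$rms_distance, 0, tolerance = 1e-9)

  moved <- apply_transform(cl, rigid_transform(diag(3), c(10, 0, 0)))
  out <- register_and_compare(moved, cl)
  expect_lt(out$metrics$mean_distance, 1e-6)
  expect_length(out$distances, n_points(cl))
  # the distance field rides along as a scalar for colorimetric export
  expect_identical(out$registered$scalar, out$distances)
})

test_that("rms >= mean for any distance field", {
  with_seed(5, {
    a <- point_cloud(matrix(runif(3000, 0, 30), ncol = 3))
    b <- point_cloud(matrix(runif(1500, 0, 30), ncol = 3))
  })
  out <- register_and_compare(a, b)
  expect_gte(out$metrics$rms_distance, out$metrics$mean_distance)
})

test_that("coverage counts intact points near the reconstruction", {
  with_seed(6, cl <- point_cloud(matrix(runif(3000, 0, 40), ncol = 3)))
  expect_equal(coverage(cl, cl, epsilon = 0.1), 1.0)

  half <- point_cloud(cl$points[cl$points[, 1] <= 20, ])
  cov_half <- coverage(half, cl, epsilon = 1.5)
  expect_gt(cov_half, 0.4)
  expect_lt(cov_half, 0.65)

  eps <- c(0.5, 1, 2, 4)
  covs <- vapply(eps, function(e) coverage(half, cl, e), numeric(1))
  expect_true(all(diff(covs) >= 0))
})

test_that("summary_stats reproduces the benchmark table rows", {
  bench <- porcine_femur_benchmark()

  fr <- summary_stats(bench$n_fragments)
  expect_equal(round_half_up(fr$mean, 1), 28.7)
  expect_equal(round_half_up(fr$sd, 1), 7.8)
  expect_equal(fr$min, 20)
  expect_equal(fr$max, 43)

  tv <- summary_stats(bench$time_vra_min)
  expect_equal(round_half_up(tv$mean, 1), 131.8)
  expect_equal(round_half_up(tv$sd, 1), 20.9)

  const <- summary_stats(rep(4.2, 5))
  expect_equal(const$sd, 0)
  expect_equal(const$mean, const$min)
  expect_equal(const$mean, const$max)
  expect_error(summary_stats(numeric(0)), "at least one")

  # matches a brute-force two-pass computation on random lists
  for (s in 1:5) {
    with_seed(s, x <- rnorm(50, 10, 3))
    st <- summary_stats(x)
    m <- sum(x) / length(x)
    expect_equal(st$mean, m, tolerance = 1e-12)
    expect_equal(st$sd, sqrt(sum((x - m)^2) / (length(x) - 1)),
                 tolerance = 1e-12)
  }
})

test_that("paired_correlation reproduces the printed coefficients", {
  bench <- porcine_femur_benchmark()
  expect_equal(round_half_up(paired_correlation(bench$time_vra_min,
                                                bench$time_pra_min), 6),
               0.711514)
  expect_equal(round_half_up(paired_correlation(bench$n_reassoc_vra,
                                                bench$n_reassoc_pra), 6),
               0.736883)

  x <- c(1, 3, 2, 5)
  expect_equal(paired_correlation(x, x), 1)
  y <- c(2, 2.5, 1, 4)
  expect_equal(paired_correlation(x, y), paired_correlation(y, x))
  expect_equal(paired_correlation(x, 3 * y + 7), paired_correlation(x, y))
  expect_error(paired_correlation(x, rep(1, 4)), "zero variance")
  expect_error(paired_correlation(x[1:2], y[1:2]), "n >= 3")

  # the intraclass variants are exposed but are distinct estimators
  icc1 <- paired_correlation(bench$time_vra_min, bench$time_pra_min,
                             method = "icc_oneway")
  expect_false(isTRUE(all.equal(icc1, 0.711514, tolerance = 1e-3)))
})

test_that("metrics validate and export as JSON + CSV", {
  expect_error(reassembly_metrics(coverage = 1.2), "coverage")
  expect_error(reassembly_metrics(n_fragments_total = 5L,
                                  n_reassociated = 7L), "exceed")
  m <- reassembly_metrics(mean_distance = 0.4, rms_distance = 0.5,
                          coverage = 0.99, n_fragments_total = 26L,
                          n_reassociated = 24L)
  d <- withr::local_tempdir()
  save_metrics(list(F1 = m), d)
  back <- jsonlite::read_json(file.path(d, "metrics.json"),
                              simplifyVector = TRUE)
  expect_equal(back$F1$mean_distance, 0.4)
  csv <- read.csv(file.path(d, "metrics.csv"))
  expect_equal(csv$n_reassociated, 24)
})
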