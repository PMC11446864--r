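# Evaluation battery: ICP registration of a reconstruction onto its intact
# reference, cloud-to-cloud distance fields, coverage, summary statistics and
# the paired-series correlation used to compare virtual against physical
# re-association.

#' Register a reconstruction onto an intact reference and compare
#'
#' The reconstruction is ICP-registered onto the intact cloud, then per-point
#' cloud-to-cloud distances are computed from the registered reconstruction
#' to the intact reference (each reconstruction point to its nearest intact
#' point; reconstruction error is the question). Both the mean and the RMS of
#' the distance field are reported — results tables in this field are
#' conventionally given as mean distances, with RMS as the companion
#' summary. The reverse-direction mean (intact to reconstruction) is included
#' as a diagnostic.
#'
#' @param recon reconstruction `point_cloud` (e.g. `$merged` of a
#'   [reassemble()] result)
#' @param intact intact reference `point_cloud`
#' @param icp_params ICP overrides; evaluation defaults are
#'   `max_corr_dist = Inf`, `trim_keep_fraction = 0.9`, `max_iter = 100`
#'   (the two models are already roughly superposed, trimming guards
#'   non-overlap)
#' @param coverage_epsilon tolerance for the coverage fraction, mm
#' @return list: `distances` (per reconstruction point, mm; exportable as a
#'   PLY scalar for colorimetric display), `registered` (the registered
#'   reconstruction), `metrics` (a `reassembly_metrics`), `icp`
#'   (the `icp_result`)
#' @export
register_and_compare <- function(recon, intact, icp_params = list(),
                                 coverage_epsilon = 2.0) {
  stopifnot(inherits(recon, "point_cloud"), inherits(intact, "point_cloud"))
  p <- utils::modifyList(list(max_corr_dist = Inf, trim_keep_fraction = 0.6,
                              max_iter = 60L, rel_tol = 1e-10,
                              subsample_n = 6000L), icp_params)
  nsub <- p$subsample_n
  p$subsample_n <- NULL
  # the reconstruction lives in an arbitrary (scattered) frame: centroid +
  # principal-axes pre-alignment, then ICP on deterministic subsamples
  sub_idx <- function(n) if (n <= nsub) seq_len(n)
    else round(seq(1, n, length.out = nsub))
  rsub <- point_cloud(recon$points[sub_idx(n_points(recon)), , drop = FALSE])
  isub <- point_cloud(intact$points[sub_idx(n_points(intact)), , drop = FALSE])
  init <- pca_prealign(rsub, isub)
  rec <- icp_refine(isub, rsub, init = init, params = p)
  registered <- apply_transform(recon, rec$transform)
  d <- as.numeric(nearest_distances(registered, intact))
  d_rev <- as.numeric(nearest_distances(intact, registered))
  cov <- mean(d_rev <= coverage_epsilon)
  metrics <- reassembly_metrics(
    mean_distance = mean(d), rms_distance = sqrt(mean(d^2)),
    coverage = cov, mean_distance_reverse = mean(d_rev))
  out <- registered
  out$scalar <- d
  list(distances = d, registered = out, metrics = metrics, icp = rec)
}

# Coarse alignment of two clouds by centroids and principal axes; the four
# proper sign combinations are scored by mean nearest distance and the best
# kept. Adequate as an ICP initializer for elongated objects.
pca_prealign <- function(mov, ref) {
  cm <- colMeans(mov$points)
  cr <- colMeans(ref$points)
  Vm <- svd(sweep(mov$points, 2, cm))$v
  Vr <- svd(sweep(ref$points, 2, cr))$v
  best <- NULL
  best_d <- Inf
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    s3 <- s1 * s2 * sign(det(Vr) * det(Vm))  # keep det(R) = +1
    R <- Vr %*% diag(c(s1, s2, s3)) %*% t(Vm)
    if (det(R) < 0) next
    tr <- rigid_transform(R, cr - as.numeric(R %*% cm))
    d <- mean(cpp_nearest(ref$points, rt_apply(tr, mov$points))$dist)
    if (d < best_d) { best_d <- d; best <- tr }
  }
  best
}

#' Reconstruction metrics container
#'
#' @param mean_distance,rms_distance mm, reconstruction-to-intact
#' @param coverage fraction of intact points within tolerance of the
#'   reconstruction
#' @param n_fragments_total,n_reassociated fragment bookkeeping
#' @param reconstruction_time_min operator-recorded wall time, minutes
#'   (recorded metadata, never measured by the package)
#' @param mean_distance_reverse diagnostic, intact-to-reconstruction mean, mm
#' @return a `reassembly_metrics` list
#' @export
reassembly_metrics <- function(mean_distance = NA_real_,
                               rms_distance = NA_real_,
                               coverage = NA_real_,
                               n_fragments_total = NA_integer_,
                               n_reassociated = NA_integer_,
                               reconstruction_time_min = NA_real_,
                               mean_distance_reverse = NA_real_) {
  if (!is.na(mean_distance) && mean_distance < 0) stop("distances must be >= 0")
  if (!is.na(coverage) && (coverage < 0 || coverage > 1))
    stop("coverage must lie in [0, 1]")
  if (!is.na(n_reassociated) && !is.na(n_fragments_total) &&
      n_reassociated > n_fragments_total)
    stop("n_reassociated cannot exceed n_fragments_total")
  structure(list(mean_distance = mean_distance, rms_distance = rms_distance,
                 coverage = coverage, n_fragments_total = n_fragments_total,
                 n_reassociated = n_reassociated,
                 reconstruction_time_min = reconstruction_time_min,
                 mean_distance_reverse = mean_distance_reverse),
            class = "reassembly_metrics")
}

#' Coverage of an intact reference by a reconstruction
#'
#' Fraction of intact points that have a reconstruction point within
#' `epsilon`. A full reconstruction is conventionally declared above 0.95.
#'
#' @param recon,intact registered `point_cloud`s
#' @param epsilon tolerance in mm (default 2.0; the published >95% criterion
#'   names none)
#' @return fraction in `[0, 1]`
#' @export
coverage <- function(recon, intact, epsilon = 2.0) {
  mean(as.numeric(nearest_distances(intact, recon)) <= epsilon)
}

#' Summary statistics (mean, sample SD, min, max, n)
#'
#' Sample standard deviation uses the n-1 denominator. Stored values are
#' never rounded; use [round_half_up()] for presentation at table precision.
#'
#' @param values numeric vector, n >= 1 (SD requires n >= 2)
#' @return a `summary_stats` list: `mean`, `sd`, `min`, `max`, `n`
#' @export
summary_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || anyNA(values))
    stop("summary_stats needs at least one non-missing value")
  structure(list(mean = mean(values),
                 sd = if (length(values) >= 2) stats::sd(values) else NA_real_,
                 min = min(values), max = max(values), n = length(values)),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("mean %.6g, sd %.6g, min %.6g, max %.6g (n = %d)\n",
              x$mean, x$sd, x$min, x$max, x$n))
  invisible(x)
}

#' Paired-series correlation between two reconstruction methods
#'
#' The default estimator is the Pearson product-moment correlation: brute
#' force comparison against published paired-series coefficients shows that
#' this — not a variance-components intraclass form — is what spreadsheet
#' "correlation" computations on such tables produce. One-way and two-way
#' (consistency) intraclass variants are exposed for comparison, clearly
#' labelled.
#'
#' @param x,y equal-length numeric series (n >= 3), e.g. per-specimen times
#'   under the virtual and the physical protocol
#' @param method `"pearson"` (default), `"icc_oneway"` or
#'   `"icc_twoway_consistency"`
#' @return the coefficient, a single number in `[-1, 1]`
#' @export
paired_correlation <- function(x, y,
                               method = c("pearson", "icc_oneway",
                                          "icc_twoway_consistency")) {
  method <- match.arg(method)
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  if (n < 3 || length(y) != n)
    stop("need equal-length series with n >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined correlation: a series has zero variance")
  switch(method,
    pearson = stats::cor(x, y),
    icc_oneway = {
      # one-way random effects, ICC(1,1)
      g <- (x + y) / 2
      msb <- 2 * stats::var(g)
      msw <- sum((x - g)^2 + (y - g)^2) / n
      (msb - msw) / (msb + msw)
    },
    icc_twoway_consistency = {
      # two-way mixed, consistency, ICC(3,1)
      g <- (x + y) / 2
      msb <- 2 * stats::var(g)
      d <- x - y
      mse <- stats::var(d) / 2
      (msb - mse) / (msb + mse)
    })
}

#' Benchmark table: six fragmented porcine femurs
#'
#' Published laboratory benchmark comparing virtual (VRA) and physical (PRA)
#' re-association of six manually fragmented porcine femurs: per-specimen
#' reconstruction times, mean reconstruction-to-intact cloud distances,
#' fragment counts and numbers of re-associated fragments. Used as reference
#' input for the evaluation-statistics operations and their tests.
#'
#' @return a data.frame with one row per specimen and columns `specimen`,
#'   `time_vra_min`, `time_pra_min`, `mean_dist_vra_mm`, `mean_dist_pra_mm`,
#'   `n_fragments`, `n_reassoc_vra`, `n_reassoc_pra`
#' @export
porcine_femur_benchmark <- function() {
  data.frame(
    specimen = c("F2.01", "F2.02", "F2.03", "F2.04", "F2.05", "F2.06"),
    time_vra_min = c(145, 120, 137, 150, 95, 144),
    time_pra_min = c(218, 177, 205, 224, 190, 252),
    mean_dist_vra_mm = c(0.8, 0.5, 1.0, 1.2, 1.3, 1.3),
    mean_dist_pra_mm = c(1.3, 0.7, 0.8, 1.2, 1.2, 1.2),
    n_fragments = c(26, 20, 31, 26, 26, 43),
    n_reassoc_vra = c(11, 8, 13, 14, 9, 19),
    n_reassoc_pra = c(17, 9, 22, 18, 9, 19),
    stringsAsFactors = FALSE)
}

#' Write evaluation metrics as JSON and CSV
#'
#' @param metrics named list of `reassembly_metrics` keyed by specimen id
#' @param dir output directory
#' @return invisibly, the JSON path
#' @export
save_metrics <- function(metrics, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "metrics.json")
  jsonlite::write_json(lapply(metrics, unclass), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  df <- do.call(rbind, lapply(names(metrics), function(id)
    data.frame(specimen = id,
               mean_distance = metrics[[id]]$mean_distance,
               rms_distance = metrics[[id]]$rms_distance,
               coverage = metrics[[id]]$coverage,
               n_fragments_total = metrics[[id]]$n_fragments_total,
               n_reassociated = metrics[[id]]$n_reassociated)))
  utils::write.csv(df, file.path(dir, "metrics.csv"), row.names = FALSE)
  invisible(path)
}
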