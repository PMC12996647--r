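test_that("target ROI masks are spheres with exhaustive-scan counts", {
  geom <- volume_geometry(c(14, 14, 14), voxel_size = c(2, 2, 2))
  tgt <- tms_target(c(0, 0, 0), "RSA")
  roi <- target_roi_mask(tgt, radius = 8, geom = geom)
  expect_identical(sum(roi$data), sphere_oracle_count(c(0, 0, 0), 8, geom))
  # sub-voxel radius on a voxel centre
  ctr <- voxel_to_world(c(7, 7, 7), geom)
  one <- target_roi_mask(tms_target(ctr, "HCA"), radius = 0.9, geom = geom)
  expect_identical(sum(one$data), 1L)
  # translation equivariance
  roi2 <- target_roi_mask(tms_target(c(2, 0, 0), "RSA"), radius = 8,
                          geom = geom)
  expect_identical(sum(roi$data & FALSE, na.rm = TRUE), 0L)
  expect_identical(sum(roi2$data), sum(roi$data))
})

test_that("ROI-to-sgACC FC matches the direct correlation formula", {
  set.seed(50)
  dims <- c(12, 1, 1); nt <- 60
  roi_series <- rnorm(nt)
  ortho <- residuals(lm(rnorm(nt) ~ roi_series))
  ts <- rbind(roi_series, roi_series, roi_series, -roi_series, ortho,
              matrix(rnorm(7 * nt), 7, nt))
  run <- run_from_matrix(ts, dims)
  geom <- tiny_geom(dims)
  roi <- mask_first_voxels(3, dims)
  sg <- binary_mask(array(c(rep(FALSE, 3), rep(TRUE, 9)), dims), geom)
  fc <- roi_sgacc_fc(run, roi, sg)
  expect_equal(fc[1], -1)
  expect_lt(abs(fc[2]), 1e-10)
  # covariance oracle for all sgACC voxels
  oracle <- apply(ts[4:12, ], 1, function(v) cor(v, roi_series))
  expect_equal(fc, unname(oracle), tolerance = 1e-12)
  # Fisher z: monotone, sign-preserving, capped
  fz <- roi_sgacc_fc(run, roi, sg, fisher_z = TRUE)
  expect_identical(sign(fz), sign(fc))
  expect_lt(max(abs(fz)), atanh(1 - 1e-7) + 1e-12)
})

test_that("voxelwise regression matches lm() and recovers a planted slope", {
  set.seed(51)
  n <- 60; nv <- 12
  fc <- matrix(rnorm(n * nv, 0, 0.2), n, nv)
  age <- round(runif(n, 19, 55)); sex <- rbinom(n, 1, 0.5)
  score <- 3 + 2 * fc[, 4] + 0.05 * age + 0.4 * sex + rnorm(n, 0, 0.05)
  st <- voxelwise_regression(fc, score, age, sex)
  # lm oracle, voxel by voxel
  for (v in c(1, 4, 9)) {
    fit <- summary(lm(score ~ fc[, v] + age + sex))
    expect_equal(st$beta[v], fit$coefficients[2, 1], tolerance = 1e-10)
    expect_equal(st$t[v], fit$coefficients[2, 3], tolerance = 1e-10)
    expect_equal(st$p[v], fit$coefficients[2, 4], tolerance = 1e-10)
  }
  expect_gt(st$beta[4], 1.8); expect_lt(st$beta[4], 2.2)
  # t for the fc coefficient is invariant to affine rescaling of age
  st2 <- voxelwise_regression(fc, score, (age - 37) / 10, sex)
  expect_equal(st$t, st2$t, tolerance = 1e-10)
  # constant fc column errors
  fc0 <- fc; fc0[, 2] <- 1
  expect_error(voxelwise_regression(fc0, score, age, sex), "constant")
})

test_that("null voxels exceed the 0.001 threshold at the nominal rate", {
  set.seed(52)
  n <- 40; nv <- 10000
  fc <- matrix(rnorm(n * nv), n, nv)
  score <- rnorm(n); age <- rnorm(n, 40, 10); sex <- rbinom(n, 1, 0.5)
  st <- voxelwise_regression(fc, score, age, sex)
  rate <- mean(st$p < 0.001)
  expect_lt(rate, 0.004)
  # two-sided p from the t distribution is uniform enough near 0.05 too
  expect_lt(abs(mean(st$p < 0.05) - 0.05), 0.02)
})

test_that("cluster thresholding keeps planted blobs and drops noise", {
  geom <- tiny_geom(c(10, 10, 10))
  mask <- binary_mask(array(TRUE, c(10, 10, 10)), geom)
  nv <- 1000
  st <- data.frame(beta = 0, t = rnorm(nv, 0, 0.5), p = runif(nv, 0.3, 0.9))
  # plant a 10-voxel contiguous positive blob
  arr <- array(FALSE, c(10, 10, 10)); arr[3:7, 5, 5] <- TRUE
  arr[3:7, 6, 5] <- TRUE
  rows <- which(as.vector(arr))
  st$p[rows] <- 1e-5; st$t[rows] <- 6
  cl <- cluster_threshold(st, mask, voxel_p = 0.001, min_size = 4)
  expect_length(cl, 1)
  expect_identical(cl[[1]]$size, 10L)
  expect_identical(cl[[1]]$direction, "positive")
  # nothing survives on a flat map
  st0 <- data.frame(beta = 0, t = rnorm(nv), p = rep(0.5, nv))
  expect_length(cluster_threshold(st0, mask), 0)
  # two 5-voxel blobs below a min_size of 6 vanish; svc vs whole-brain edge
  st2 <- st0
  blob1 <- which(as.vector({z <- array(FALSE, c(10,10,10)); z[1:5,1,1] <- TRUE; z}))
  blob2 <- which(as.vector({z <- array(FALSE, c(10,10,10)); z[1:5,10,10] <- TRUE; z}))
  st2$p[c(blob1, blob2)] <- 1e-5; st2$t[c(blob1, blob2)] <- 5
  expect_length(cluster_threshold(st2, mask, min_size = 6), 0)
  expect_length(cluster_threshold(st2, mask, min_size = 5, mode = "svc"), 2)
  expect_length(cluster_threshold(st2, mask, min_size = 5,
                                  mode = "whole_brain"), 0)
})

test_that("the permutation cluster-size null is reproducible and monotone", {
  set.seed(53)
  dims <- c(6, 6, 6)
  geom <- tiny_geom(dims)
  mask <- binary_mask(array(TRUE, dims), geom)
  n <- 30; nv <- prod(dims)
  fc <- matrix(rnorm(n * nv), n, nv)
  score <- rnorm(n); age <- rnorm(n, 40, 8); sex <- rbinom(n, 1, 0.5)
  r1 <- cluster_size_null(fc, score, age, sex, mask, n_perm = 120, seed = 7)
  r2 <- cluster_size_null(fc, score, age, sex, mask, n_perm = 120, seed = 7)
  expect_identical(as.numeric(r1), as.numeric(r2))
  # pure noise: recommended minimum stays small
  expect_lte(as.numeric(r1), 4)
  # stricter voxel_p can only shrink null clusters
  r_loose <- suppressWarnings(
    cluster_size_null(fc, score, age, sex, mask, voxel_p = 0.05,
                      n_perm = 60, seed = 9))
  r_strict <- suppressWarnings(
    cluster_size_null(fc, score, age, sex, mask, voxel_p = 0.001,
                      n_perm = 60, seed = 9))
  expect_lte(as.numeric(r_strict), as.numeric(r_loose))
  expect_warning(cluster_size_null(fc, score, age, sex, mask, n_perm = 50,
                                   seed = 3), "unstable")
})

test_that("the full symptom path works on a small simulated cohort", {
  # global component off: this checks the FC measurement path itself,
  # not the global-signal confound (covered by the GSR tests)
  spec <- cohort_spec(n_subjects = 6, runs_per_subject = 1, nt = 120,
                      symptom_noise_sd = 0.2, global_amp = 0, seed = 77)
  co <- simulate_cohort_with_scores(spec)
  m <- co$masks
  fc <- t(vapply(co$subjects, function(s) {
    run <- bandpass(s$runs[[1]], 0.01, 0.1)
    roi <- target_roi_mask(tms_target(s$truth$blob_centroid, "RSA"),
                           radius = 8, geom = m$geometry)
    roi_sgacc_fc(run, roi, m$sgacc)
  }, numeric(mask_count(m$sgacc))))
  expect_identical(dim(fc), c(6L, mask_count(m$sgacc)))
  expect_true(all(is.finite(fc)))
  # the planted anticorrelation shows up in the measured FC
  expect_lt(mean(fc), 0)
  st <- voxelwise_regression(fc, co$scores$score, co$scores$age,
                             co$scores$sex)
  expect_identical(nrow(st), mask_count(m$sgacc))
})
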