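test_that("seed FC maps match the direct correlation formula", {
  set.seed(30)
  dims <- c(10, 1, 1); nt <- 40
  seedv <- rnorm(nt)
  ts <- rbind(seedv, -seedv, matrix(rnorm(8 * nt), 8, nt))
  run <- run_from_matrix(ts, dims)
  geom <- tiny_geom(dims)
  seed_mask <- mask_first_voxels(1, dims)
  brain <- binary_mask(array(TRUE, dims), geom)
  fc <- sgacc_fc_map(run, seed_mask, brain)
  vals <- fc$data[, 1, 1]
  expect_equal(vals[1], 1)
  expect_equal(vals[2], -1)
  # covariance oracle on the remaining voxels
  oracle <- apply(ts, 1, function(v)
    sum((v - mean(v)) * (seedv - mean(seedv))) /
      sqrt(sum((v - mean(v))^2) * sum((seedv - mean(seedv))^2)))
  expect_equal(vals, unname(oracle), tolerance = 1e-12)
})

test_that("group weight maps average voxelwise and are NaN-aware", {
  geom <- tiny_geom(c(4, 4, 4))
  mk <- function(vals) weight_map(array(vals, dim = c(4, 4, 4)), geom)
  single <- mk(runif(64))
  expect_equal(group_weight_map(list(single))$data, single$data)
  expect_true(all(group_weight_map(list(mk(0.4), mk(-0.4)))$data == 0))
  set.seed(31)
  maps <- lapply(1:5, function(i) mk(rnorm(64)))
  gw <- group_weight_map(maps)
  oracle <- array(0, dim = c(4, 4, 4))
  for (i in seq_len(64)) {
    v <- vapply(maps, function(m) m$data[[i]], numeric(1))
    oracle[[i]] <- mean(v)
  }
  expect_equal(gw$data, oracle, tolerance = 1e-12)
  # NaN only when all maps are NaN there
  m1 <- mk(rep(0.2, 64)); m2 <- mk(rep(0.6, 64))
  m1$data[1, 1, 1] <- NA; m2$data[1, 1, 1] <- NA; m2$data[2, 1, 1] <- NA
  gw2 <- group_weight_map(list(m1, m2))
  expect_true(is.na(gw2$data[1, 1, 1]))
  expect_equal(gw2$data[2, 1, 1], 0.2)
})

test_that("the weighted representative signal follows the formula", {
  dims <- c(4, 1, 1); nt <- 6
  ts <- rbind(rep(1, nt), seq_len(nt), rep(2, nt), rep(9, nt))
  run <- run_from_matrix(ts, dims)
  geom <- tiny_geom(dims)
  brain <- binary_mask(array(c(TRUE, TRUE, TRUE, FALSE), dim = dims), geom)
  dlpfc <- binary_mask(array(c(FALSE, FALSE, FALSE, FALSE), dim = dims),
                       geom, require_nonempty = FALSE)
  dlpfc$data[4] <- TRUE  # keep DLPFC disjoint from the averaging set
  w <- weight_map(array(c(1, -1, 2, 0), dim = dims), geom)
  s <- weighted_representative_signal(run, w, dlpfc, brain)
  expect_equal(as.numeric(s), (1 * ts[1, ] - 1 * ts[2, ] + 2 * ts[3, ]) / 3)
  # unit weights reduce to the plain mean outside the DLPFC
  w1 <- weight_map(array(1, dim = dims), geom)
  expect_equal(as.numeric(weighted_representative_signal(run, w1, dlpfc,
                                                         brain)),
               colMeans(ts[1:3, ]))
  # all-zero weights are flagged as degenerate
  w0 <- weight_map(array(0, dim = dims), geom)
  expect_warning(s0 <- weighted_representative_signal(run, w0, dlpfc, brain),
                 "degenerate")
  expect_true(all(s0 == 0))
})

test_that("retain_top_fraction keeps the most anticorrelated fraction", {
  keep <- retain_top_fraction(c(-0.9, -0.1, 0.2, 0.8), 0.5)
  expect_identical(which(keep), c(1L, 2L))
  expect_identical(which(retain_top_fraction(c(-0.9, -0.1, 0.2, 0.8), 1.0)),
                   1:4)
  # sort oracle across all ten sweep fractions
  set.seed(32)
  x <- runif(1000, -1, 1)
  for (f in seq(0.1, 1, by = 0.1)) {
    keep <- retain_top_fraction(x, f)
    k <- round(f * 1000)
    expect_identical(sum(keep), as.integer(k))
    if (any(!keep)) expect_true(max(x[keep]) <= min(x[!keep]))
  }
  # descending option retains the other tail
  kd <- retain_top_fraction(c(-0.9, -0.1, 0.2, 0.8), 0.5, "descending")
  expect_identical(which(kd), c(3L, 4L))
  expect_error(retain_top_fraction(numeric(0), 0.5), "no voxels")
  expect_error(retain_top_fraction(c(1, 2), 0), "fraction")
})

test_that("retained sets are nested and monotone across the sweep", {
  set.seed(33)
  x <- rnorm(400)
  prev <- NULL
  for (f in seq(0.1, 1, by = 0.1)) {
    keep <- retain_top_fraction(x, f)
    if (!is.null(prev)) expect_true(all(keep[prev]))
    prev <- keep
  }
})

test_that("largest_connected_cluster matches the flood-fill oracle", {
  set.seed(34)
  for (rep in 1:10) {
    m <- random_mask(c(8, 8, 8), runif(1, 0.1, 0.5))
    if (!any(m$data)) next
    for (conn in c(6, 18, 26)) {
      labels <- connected_components(m, conn)
      oracle <- flood_fill_components(m, conn)
      expect_true(same_partition(labels[labels > 0], oracle[oracle > 0]))
      big <- largest_connected_cluster(m, conn)
      sizes <- tabulate(oracle[oracle > 0])
      expect_identical(sum(big$data), max(sizes))
    }
  }
  # two blobs: the larger wins; a single voxel is its own cluster
  dims <- c(10, 3, 3)
  arr <- array(FALSE, dims)
  arr[1:5, 1, 1] <- TRUE; arr[8:10, 1, 1] <- TRUE
  m2 <- binary_mask(arr, tiny_geom(dims))
  expect_identical(which(largest_connected_cluster(m2, 26)$data),
                   which(arr)[1:5])
})

test_that("cluster centroids are coordinate means in world mm", {
  dims <- c(6, 6, 6)
  geom <- tiny_geom(dims, voxel_size = 2, origin = c(0, 0, 0))
  arr <- array(FALSE, dims)
  arr[1, 1, 1] <- TRUE; arr[2, 1, 1] <- TRUE
  expect_equal(cluster_centroid(binary_mask(arr, geom)), c(1, 0, 0))
  # symmetric cube centred on its geometric centre
  arr2 <- array(FALSE, dims); arr2[2:4, 2:4, 2:4] <- TRUE
  expect_equal(cluster_centroid(binary_mask(arr2, geom)), c(4, 4, 4))
  # loop oracle on random voxels
  set.seed(35)
  m <- random_mask(dims, 0.3, geom)
  w <- voxel_to_world(mask_voxel_matrix(m), geom)
  expect_equal(cluster_centroid(m), colMeans(w))
})

test_that("rsa_target recovers the planted blob and composes correctly", {
  ps <- planted_subject()
  sub <- ps$sub; m <- sub$masks
  run <- preprocess_run(sub$runs[[1]], fwhm = 5, motion = sub$motion[[1]],
                        wm_csf_mask = binary_mask(m$wm$data | m$csf$data,
                                                  m$geometry, name = "wmcsf"),
                        brain_mask = m$brain)
  fc <- sgacc_fc_map(run, m$sgacc, m$brain)
  w <- group_weight_map(list(fc))
  tgt <- rsa_target(run, w, m$dlpfc, m$brain, fraction = 0.5)
  # target within the planted blob's bounding box
  bb <- apply(mask_world_coords(m$target_blob), 2, range)
  expect_true(all(tgt$world_mm >= bb[1, ] & tgt$world_mm <= bb[2, ]))
  # determinism
  tgt2 <- rsa_target(run, w, m$dlpfc, m$brain, fraction = 0.5)
  expect_identical(tgt$world_mm, tgt2$world_mm)
  # fraction 1.0 reduces to the centroid of the whole mask's largest
  # connected component
  t_all <- rsa_target(run, w, m$dlpfc, m$brain, fraction = 1)
  expect_equal(t_all$world_mm,
               cluster_centroid(largest_connected_cluster(m$dlpfc, 26)))
  # the centroid lies inside the convex hull of the retained cluster
  # (coordinate-wise bounding box is a necessary envelope)
  cl <- attr(tgt, "cluster")
  bbcl <- apply(mask_world_coords(cl), 2, range)
  expect_true(all(tgt$world_mm >= bbcl[1, ] & tgt$world_mm <= bbcl[2, ]))
})
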