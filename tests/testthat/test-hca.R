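test_that("Spearman distances match the rank-then-Pearson oracle", {
  set.seed(20)
  ts <- matrix(rnorm(6 * 20), 6, 20)
  d <- spearman_distance_matrix(ts)
  ranks <- t(apply(ts, 1, rank))
  oracle <- 1 - stats::cor(t(ranks))
  diag(oracle) <- 0
  expect_equal(d, oracle, tolerance = 1e-12)
  expect_true(isSymmetric(d))
  expect_true(all(d >= 0 & d <= 2))
  # identical and perfectly opposed series
  ts2 <- rbind(1:10, 1:10, 10:1)
  d2 <- spearman_distance_matrix(ts2)
  expect_equal(d2[1, 2], 0)
  expect_equal(d2[1, 3], 2)
  expect_error(spearman_distance_matrix(rbind(rep(1, 10), 1:10)), "constant")
})

test_that("two-voxel merges follow the stopping threshold", {
  adj <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2)
  d_close <- matrix(c(0, 0.3, 0.3, 0), 2, 2)
  d_far <- matrix(c(0, 0.7, 0.7, 0), 2, 2)
  expect_identical(constrained_agglomerative_cluster(d_close, adj), c(1L, 1L))
  expect_identical(constrained_agglomerative_cluster(d_far, adj), c(1L, 2L))
  # non-adjacent voxels never merge however close
  noadj <- matrix(FALSE, 2, 2)
  expect_identical(constrained_agglomerative_cluster(d_close, noadj),
                   c(1L, 2L))
})

test_that("clustering matches the exhaustive greedy-merge oracle on lines", {
  set.seed(21)
  for (rep in 1:20) {
    n <- 10
    vox <- cbind(seq_len(n), 1L, 1L)  # a line graph under 6-connectivity
    adj <- voxel_adjacency(vox, 6)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(sum(upper.tri(d)), 0, 1.2)
    d <- d + t(d)
    labels <- constrained_agglomerative_cluster(d, adj, 0.5)
    oracle <- greedy_merge_oracle(d, adj, 0.5)
    expect_true(same_partition(labels, oracle))
  }
})

test_that("clustering labels are invariant to voxel enumeration order", {
  set.seed(22)
  dims <- c(4, 4, 3)
  m <- random_mask(dims, 0.5)
  vox <- mask_voxel_matrix(m)
  n <- nrow(vox)
  ts <- matrix(rnorm(n * 30), n, 30)
  d <- spearman_distance_matrix(ts)
  adj <- voxel_adjacency(vox, 26)
  ref <- constrained_agglomerative_cluster(d, adj, 0.6)
  perm <- sample(n)
  lab_p <- constrained_agglomerative_cluster(d[perm, perm],
                                             adj[perm, perm], 0.6)
  # map permuted labels back to original order
  back <- integer(n)
  back[perm] <- lab_p
  expect_true(same_partition(ref, back))
})

test_that("disconnected mask components always stay separate", {
  vox <- rbind(c(1, 1, 1), c(2, 1, 1), c(6, 1, 1), c(7, 1, 1))
  adj <- voxel_adjacency(vox, 26)
  d <- matrix(0.01, 4, 4); diag(d) <- 0
  labels <- constrained_agglomerative_cluster(d, adj, 0.5)
  expect_identical(length(unique(labels)), 2L)
  expect_identical(labels[1], labels[2])
  expect_false(labels[1] == labels[3])
})

test_that("subunit summaries compute medians, representatives, concentration", {
  geom <- tiny_geom(c(8, 1, 1), voxel_size = 2)
  vox <- cbind(1:4, 1L, 1L)
  set.seed(23)
  base <- rnorm(30)
  ts <- rbind(base, base + rnorm(30, 0, 0.1), base + rnorm(30, 0, 2),
              rnorm(30))
  su <- subunit_summary(ts, c(1L, 1L, 1L, 2L), vox, geom)
  expect_length(su$subunits, 2)
  s1 <- su$subunits[[1]]
  med <- apply(ts[1:3, ], 2, median)
  expect_equal(s1$median_timecourse, med)
  # representative = member with max Pearson correlation to the median
  cors <- cor(t(ts[1:3, ]), med)
  expect_equal(s1$representative_voxel, vox[which.max(cors), ])
  # concentration: 3 voxels spanning 2 and 4 mm pairwise
  pw <- c(2, 4, 2)
  expect_equal(s1$concentration, 3 / mean(pw))
  # singleton: its own series, representative itself, concentration 0
  s2 <- su$subunits[[2]]
  expect_equal(s2$median_timecourse, ts[4, ])
  expect_equal(s2$representative_voxel, vox[4, ])
  expect_identical(s2$concentration, 0)
  # a 2-voxel subunit 4 mm apart has concentration 2/4
  su2 <- subunit_summary(ts[c(1, 3), ], c(1L, 1L), cbind(c(1L, 3L), 1L, 1L),
                         geom)
  expect_equal(su2$subunits[[1]]$concentration, 0.5)
})

test_that("subunit scoring matches a hand computation on a 3x2 toy", {
  nt <- 40
  set.seed(24)
  # three DLPFC representatives with controlled correlations to two sgACC
  # representatives of sizes 10 and 5
  sg1 <- rnorm(nt); sg2 <- rnorm(nt)
  fake_set <- function(series, sizes, concs) {
    structure(list(subunits = Map(function(s, n, cc)
      list(representative_series = s, size = n, concentration = cc),
      series, sizes, concs)), class = "subunit_set")
  }
  d1 <- -sg1 + rnorm(nt, 0, 0.3)
  d2 <- sg2 + rnorm(nt, 0, 0.3)
  d3 <- rnorm(nt)
  dl <- fake_set(list(d1, d2, d3), c(20L, 8L, 5L), c(4, 2, 1))
  sg <- fake_set(list(sg1, sg2), c(10L, 5L), c(3, 3))
  sc <- score_subunits(dl, sg)
  # oracle: explicit spreadsheet arithmetic
  w <- vapply(list(d1, d2, d3), function(s)
    10 * cor(s, sg1) + 5 * cor(s, sg2), numeric(1))
  z <- function(x) (x - mean(x)) / sd(x)
  expect_equal(sc$weighted_corr_sum, w, tolerance = 1e-12)
  expect_equal(sc$z_weighted, z(w), tolerance = 1e-12)
  expect_equal(sc$z_size, z(c(20, 8, 5)), tolerance = 1e-12)
  expect_equal(sc$z_conc, z(c(4, 2, 1)), tolerance = 1e-12)
  expect_equal(sc$composite, z(w) + z(c(4, 2, 1)) + z(c(20, 8, 5)),
               tolerance = 1e-12)
  # z-columns have mean 0 and SD 1
  for (col in c("z_weighted", "z_conc", "z_size")) {
    expect_lt(abs(mean(sc[[col]])), 1e-12)
    expect_lt(abs(sd(sc[[col]]) - 1), 1e-12)
  }
})

test_that("degenerate scoring cases follow the documented conventions", {
  nt <- 30
  set.seed(25)
  sg1 <- rnorm(nt)
  fake_set <- function(series, sizes, concs) {
    structure(list(subunits = Map(function(s, n, cc)
      list(representative_series = s, size = n, concentration = cc),
      series, sizes, concs)), class = "subunit_set")
  }
  sg <- fake_set(list(sg1), 10L, 3)
  # identical parameter triples: zero-variance z columns become zeros
  s <- rnorm(nt)
  dl <- fake_set(list(s, s), c(4L, 4L), c(2, 2))
  sc <- score_subunits(dl, sg)
  expect_true(all(sc$composite == 0))
  # weighted sums: r = (-0.5, +0.5) with one sgACC subunit of n = 10
  d1 <- -sg1; d2 <- sg1
  sc2 <- score_subunits(fake_set(list(d1, d2), c(4L, 4L), c(2, 2)), sg)
  expect_equal(sc2$weighted_corr_sum, c(-10, 10), tolerance = 1e-10)
  # a single DLPFC subunit cannot be z-scored
  expect_error(score_subunits(fake_set(list(s), 4L, 2), sg), ">= 2")
})

test_that("hca_target finds the planted anticorrelated blob, deterministically", {
  ps <- planted_subject()
  sub <- ps$sub; m <- sub$masks
  run <- preprocess_run(sub$runs[[1]], fwhm = 5, motion = sub$motion[[1]],
                        wm_csf_mask = binary_mask(m$wm$data | m$csf$data,
                                                  m$geometry, name = "wmcsf"),
                        brain_mask = m$brain)
  t1 <- hca_target(run, m$dlpfc, m$sgacc)
  idx <- world_to_voxel(t1$world_mm, m$geometry)
  expect_true(m$target_blob$data[idx[1], idx[2], idx[3]])
  expect_true(m$dlpfc$data[idx[1], idx[2], idx[3]])
  # determinism
  t2 <- hca_target(run, m$dlpfc, m$sgacc)
  expect_identical(t1$world_mm, t2$world_mm)
})
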