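#' Spherical ROI around a derived target
#'
#' 8-mm-radius sphere (by default) centred on the target coordinate, used to
#' extract the target's mean time series for the symptom-association
#' analysis.
#'
#' @param target a [tms_target()] or mm triple.
#' @param radius sphere radius in mm (default 8).
#' @param geom a [volume_geometry()].
#' @return a [binary_mask()].
#' @export
target_roi_mask <- function(target, radius = 8, geom) {
  make_sphere_mask(target_coords(target), radius, geom, name = "target_roi")
}

#' Target-to-sgACC functional connectivity vector
#'
#' Correlates the ROI mean time series with each sgACC voxel; optionally
#' Fisher-z transforms (`atanh`) the correlations, with |r| clamped to
#' `1 - 1e-7` so the transform stays finite (|z| capped at about 8.4).
#'
#' @param run a preprocessed [bold_run()].
#' @param roi target [binary_mask()] (see [target_roi_mask()]).
#' @param sgacc sgACC [binary_mask()].
#' @param fisher_z apply the z-transform (default `FALSE`).
#' @return numeric vector, one value per sgACC voxel in mask order.
#' @export
roi_sgacc_fc <- function(run, roi, sgacc, fisher_z = FALSE) {
  s <- rowMeans(mask_timeseries(run, roi))
  if (stats::sd(s) == 0) stop("ROI mean series has zero variance")
  ts <- mask_timeseries(run, sgacc)
  r <- suppressWarnings(as.vector(stats::cor(ts, s)))
  r[is.na(r)] <- 0
  if (fisher_z) r <- atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))
  r
}

#' Voxel-wise symptom regression over the sgACC
#'
#' Per sgACC voxel, fits `score ~ intercept + fc + age + sex` by OLS and
#' reports the FC coefficient's estimate, t statistic and two-sided p-value
#' from the t distribution with n - 4 degrees of freedom.
#'
#' @param fc n_subjects x n_voxels matrix of target-sgACC FC values.
#' @param score numeric symptom scores (length n_subjects).
#' @param age,sex covariates (sex coded 0/1).
#' @return data.frame with one row per voxel: `beta`, `t`, `p`.
#' @export
voxelwise_regression <- function(fc, score, age, sex) {
  fc <- as.matrix(fc)
  n <- nrow(fc)
  if (length(score) != n || length(age) != n || length(sex) != n)
    stop("'score', 'age' and 'sex' must each have one value per subject")
  if (n <= 4L) stop("need more subjects than regressors (n > 4)")
  if (anyNA(fc) || anyNA(score) || anyNA(age) || anyNA(sex))
    stop("NA values in the cohort data")
  Z <- cbind(1, age, sex)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) stop("rank-deficient covariate design")
  # Frisch-Waugh: partial score and each fc column out of the covariates
  rs <- qr.resid(qz, score)
  rf <- qr.resid(qz, fc)
  sxx <- colSums(rf^2)
  if (any(sxx < 1e-24))
    stop("fc column constant (or collinear with covariates) at voxel ",
         which(sxx < 1e-24)[1])
  beta <- colSums(rf * rs) / sxx
  df <- n - 4L
  rss <- sum(rs^2) - beta^2 * sxx
  rss <- pmax(rss, 0)
  se <- sqrt(rss / df / sxx)
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
  data.frame(beta = beta, t = tval, p = pval)
}

#' Cluster-extent thresholding of a voxel-wise map
#'
#' Thresholds at `p < voxel_p`, splits suprathreshold voxels by the sign of
#' t, labels connected components, and reports clusters meeting the size
#' rule: `size >= min_size` in small-volume-correction mode (the default,
#' mirroring "minimum cluster size of 4"), or `size > min_size` in
#' whole-brain mode (mirroring "cluster size > 18").
#'
#' @param stats data.frame from [voxelwise_regression()] (columns `t`, `p`),
#'   one row per voxel of `mask`.
#' @param mask the analysis [binary_mask()] whose voxels the rows describe.
#' @param voxel_p voxel-wise p threshold (default 0.001).
#' @param min_size cluster-size threshold in voxels (default 4).
#' @param connectivity contiguity rule (default 26).
#' @param mode "svc" (`>=`) or "whole_brain" (`>`).
#' @return list of clusters, each with `voxels` (index matrix), `size`,
#'   `direction`, `peak_voxel`, `peak_t`, `centroid_mm`. Empty list if
#'   nothing survives.
#' @export
cluster_threshold <- function(stats, mask, voxel_p = 0.001, min_size = 4,
                              connectivity = 26,
                              mode = c("svc", "whole_brain")) {
  mode <- match.arg(mode)
  vox <- mask_voxel_matrix(mask)
  if (nrow(vox) != nrow(stats))
    stop("'stats' rows must match the mask voxel count")
  out <- list()
  for (dir in c("positive", "negative")) {
    sel <- stats$p < voxel_p &
      (if (dir == "positive") stats$t > 0 else stats$t < 0)
    if (!any(sel)) next
    sub <- array(FALSE, dim = mask$geometry$dims)
    sub[vox[sel, , drop = FALSE]] <- TRUE
    labels <- connected_components(
      binary_mask(sub, mask$geometry, require_nonempty = FALSE),
      connectivity)
    for (id in seq_len(max(labels))) {
      cl_vox <- which(labels == id, arr.ind = TRUE, useNames = FALSE)
      sz <- nrow(cl_vox)
      keep <- if (mode == "svc") sz >= min_size else sz > min_size
      if (!keep) next
      rows <- match(apply(cl_vox, 1, paste, collapse = ","),
                    apply(vox, 1, paste, collapse = ","))
      tvals <- stats$t[rows]
      pk <- which.max(abs(tvals))
      out[[length(out) + 1L]] <- list(
        voxels = cl_vox, size = sz, direction = dir,
        peak_voxel = cl_vox[pk, ], peak_t = tvals[pk],
        centroid_mm = colMeans(voxel_to_world(cl_vox, mask$geometry)))
    }
  }
  out[order(-vapply(out, `[[`, numeric(1), "size"))]
}

#' Permutation-based cluster-size null
#'
#' Permutes the symptom scores across subjects, re-runs the voxel-wise
#' regression and thresholding, and returns the 95th percentile of the
#' maximum null cluster size — a data-driven recommendation for `min_size`.
#'
#' @inheritParams voxelwise_regression
#' @param mask the sgACC [binary_mask()].
#' @param voxel_p voxel-wise p threshold (default 0.001).
#' @param connectivity contiguity rule (default 26).
#' @param n_perm number of permutations (default 1000; < 100 warns).
#' @param seed integer seed.
#' @return recommended minimum cluster size (95th percentile of max null
#'   cluster sizes); the null sizes are attached as attribute `"null_sizes"`.
#' @export
cluster_size_null <- function(fc, score, age, sex, mask, voxel_p = 0.001,
                              connectivity = 26, n_perm = 1000, seed) {
  if (missing(seed)) stop("'seed' is required for reproducibility")
  if (n_perm < 100) warning("n_perm < 100 gives an unstable 95th percentile")
  set.seed(as.integer(seed))
  n <- length(score)
  max_sizes <- vapply(seq_len(n_perm), function(i) {
    st <- voxelwise_regression(fc, score[sample.int(n)], age, sex)
    cl <- cluster_threshold(st, mask, voxel_p = voxel_p, min_size = 1,
                            connectivity = connectivity, mode = "svc")
    if (length(cl)) max(vapply(cl, `[[`, numeric(1), "size")) else 0
  }, numeric(1))
  rec <- stats::quantile(max_sizes, 0.95, names = FALSE, type = 1)
  attr(rec, "null_sizes") <- max_sizes
  rec
}
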