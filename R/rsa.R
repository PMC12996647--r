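#' Seed-based sgACC functional connectivity map
#'
#' Averages the time series over the sgACC seed mask and correlates it
#' (Pearson) with every voxel inside the brain mask; voxels outside the
#' brain are `NA`.
#'
#' @param run a preprocessed [bold_run()].
#' @param sgacc_mask seed [binary_mask()].
#' @param brain_mask analysis [binary_mask()].
#' @return a [weight_map()] of correlation values with attribute
#'   `"seed_name"`.
#' @export
sgacc_fc_map <- function(run, sgacc_mask, brain_mask) {
  seed <- rowMeans(mask_timeseries(run, sgacc_mask))
  if (stats::sd(seed) == 0) stop("seed series has zero variance")
  ts <- mask_timeseries(run, brain_mask)  # nt x nvox
  r <- suppressWarnings(as.vector(stats::cor(ts, seed)))
  vol <- array(NA_real_, dim = run$geometry$dims)
  vol[as.vector(brain_mask$data)] <- r
  w <- weight_map(vol, run$geometry, name = "sgacc_fc")
  attr(w, "seed_name") <- sgacc_mask$name
  w
}

#' Population-based weighting mask
#'
#' Voxelwise arithmetic mean of individual seed-connectivity maps; a voxel
#' is `NA` only where it is `NA` in every map. Optionally Fisher-z
#' transforms the maps before averaging.
#'
#' @param maps list of [weight_map()]s sharing one geometry.
#' @param fisher_z average `atanh(r)` instead of raw r (default `FALSE`).
#' @return a [weight_map()].
#' @export
group_weight_map <- function(maps, fisher_z = FALSE) {
  if (length(maps) < 1L) stop("need at least one map")
  geom <- maps[[1]]$geometry
  for (m in maps) if (!geom_equal(m$geometry, geom))
    stop("all maps must share one geometry")
  stack <- vapply(maps, function(m) {
    v <- as.vector(m$data)
    if (fisher_z) atanh(pmin(pmax(v, -1 + 1e-7), 1 - 1e-7)) else v
  }, numeric(prod(geom$dims)))
  if (is.null(dim(stack))) stack <- matrix(stack, ncol = length(maps))
  avg <- rowMeans(stack, na.rm = TRUE)
  avg[!is.finite(avg)] <- NA_real_
  if (fisher_z) avg <- tanh(avg)
  weight_map(array(avg, dim = geom$dims), geom, name = "group_weight")
}

#' Weighted sgACC representative signal
#'
#' Multiplies the run data by the weighting mask and averages the resulting
#' time series over all brain voxels outside the DLPFC mask; weights are
#' used with their sign (anticorrelated voxels contribute negatively).
#' `NA` weights are treated as 0.
#'
#' @param run a preprocessed [bold_run()].
#' @param w a [weight_map()].
#' @param dlpfc_mask,brain_mask [binary_mask()]s; `brain \ DLPFC` must be
#'   non-empty.
#' @return numeric time series of length nt; attribute `"degenerate"` is
#'   `TRUE` when all usable weights are zero.
#' @export
weighted_representative_signal <- function(run, w, dlpfc_mask, brain_mask) {
  stopifnot_same_geometry(run, w)
  stopifnot_same_geometry(run, dlpfc_mask)
  stopifnot_same_geometry(run, brain_mask)
  sel <- brain_mask$data & !dlpfc_mask$data
  if (!any(sel)) stop("'brain \\ DLPFC' averaging set is empty")
  selmask <- binary_mask(sel, run$geometry, name = "outside_dlpfc")
  ts <- mask_timeseries(run, selmask)          # nt x nvox
  wv <- w$data[sel]
  wv[is.na(wv)] <- 0
  s <- as.vector(ts %*% wv) / length(wv)
  degenerate <- all(wv == 0)
  if (degenerate)
    warning("all weights are zero outside the DLPFC; representative ",
            "signal is degenerate")
  attr(s, "degenerate") <- degenerate
  s
}

#' Retain the top fraction of ranked voxels
#'
#' Sorts the per-voxel correlations ascending (most anticorrelated first)
#' and retains the first `round(fraction * N)` voxels (at least one); ties
#' are broken by voxel index. `rank_order = "descending"` retains the
#' most positively correlated fraction instead (sensitivity analysis).
#'
#' @param corr numeric correlations, one per DLPFC voxel (mask order).
#' @param fraction fraction in (0, 1]; default 0.5, swept 0.1..1.0 in the
#'   robustness analysis.
#' @param rank_order "ascending" (default) or "descending".
#' @return logical vector marking the retained voxels; attributes
#'   `"fraction"` and `"n_retained"`.
#' @export
retain_top_fraction <- function(corr, fraction = 0.5,
                                rank_order = c("ascending", "descending")) {
  rank_order <- match.arg(rank_order)
  n <- length(corr)
  if (n == 0L) stop("no voxels to rank")
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("'fraction' must be in (0, 1]")
  if (anyNA(corr)) stop("correlations must not contain NA")
  k <- max(1L, as.integer(round(fraction * n)))
  ord <- if (rank_order == "ascending") order(corr, seq_len(n))
         else order(-corr, seq_len(n))
  keep <- logical(n)
  keep[ord[seq_len(k)]] <- TRUE
  attr(keep, "fraction") <- fraction
  attr(keep, "n_retained") <- k
  keep
}

#' Refined seed-based target derivation
#'
#' Full RSA pipeline for one preprocessed run: build the weighted sgACC
#' representative signal from all brain voxels outside the DLPFC, correlate
#' it with every DLPFC voxel, retain the most anticorrelated `fraction` of
#' voxels, and return the centroid of the largest contiguous retained
#' cluster as the stimulation target.
#'
#' @param run a preprocessed [bold_run()].
#' @param w population-based [weight_map()] (see [group_weight_map()]).
#' @param dlpfc_mask,brain_mask [binary_mask()]s.
#' @param fraction retained fraction in (0, 1] (default 0.5).
#' @param connectivity contiguity rule for the cluster step (default 26).
#' @param rank_order see [retain_top_fraction()].
#' @return a [tms_target()]; the retained mask is attached as attribute
#'   `"retained"`.
#' @export
rsa_target <- function(run, w, dlpfc_mask, brain_mask, fraction = 0.5,
                       connectivity = 26,
                       rank_order = c("ascending", "descending")) {
  rank_order <- match.arg(rank_order)
  s <- weighted_representative_signal(run, w, dlpfc_mask, brain_mask)
  ts <- mask_timeseries(run, dlpfc_mask)
  corr <- suppressWarnings(as.vector(stats::cor(ts, s)))
  corr[is.na(corr)] <- 0
  keep <- retain_top_fraction(corr, fraction, rank_order)
  vox <- mask_voxel_matrix(dlpfc_mask)
  ret <- array(FALSE, dim = run$geometry$dims)
  ret[vox[keep, , drop = FALSE]] <- TRUE
  retained <- binary_mask(ret, run$geometry, name = "rsa_retained")
  cl <- largest_connected_cluster(retained, connectivity)
  tgt <- tms_target(cluster_centroid(cl), "RSA",
                    subject_id = run$subject_id, day = run$day,
                    phase = run$phase,
                    params = list(fraction = fraction,
                                  connectivity = connectivity,
                                  rank_order = rank_order))
  attr(tgt, "retained") <- retained
  attr(tgt, "cluster") <- cl
  tgt
}

#' Fraction sweep of RSA targets
#'
#' Derives one target per retained fraction (default 10%..100% in 10%
#' steps).
#'
#' @inheritParams rsa_target
#' @param fractions numeric vector of fractions.
#' @return a list of [tms_target()]s named by fraction.
#' @export
rsa_target_sweep <- function(run, w, dlpfc_mask, brain_mask,
                             fractions = seq(0.1, 1, by = 0.1),
                             connectivity = 26) {
  out <- lapply(fractions, function(f)
    rsa_target(run, w, dlpfc_mask, brain_mask, fraction = f,
               connectivity = connectivity))
  names(out) <- sprintf("%.0f%%", 100 * fractions)
  out
}
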