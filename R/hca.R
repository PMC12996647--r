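#' Derived stimulation target
#'
#' A single target coordinate in world (MNI) mm, with provenance: which
#' algorithm produced it, for which subject/run, under which parameters.
#'
#' @param world_mm finite mm triple.
#' @param algorithm "HCA" or "RSA".
#' @param subject_id,day,phase run metadata.
#' @param params named list of algorithm parameters (threshold, gsr flag, ...).
#' @return an object of class `tms_target`.
#' @export
tms_target <- function(world_mm, algorithm, subject_id = NA_character_,
                       day = NA_integer_, phase = NA_character_,
                       params = list()) {
  world_mm <- as.numeric(world_mm)
  if (length(world_mm) != 3L || !all(is.finite(world_mm)))
    stop("target coordinates must be a finite mm triple")
  algorithm <- match.arg(algorithm, c("HCA", "RSA"))
  structure(list(world_mm = world_mm, algorithm = algorithm,
                 subject_id = subject_id, day = day, phase = phase,
                 params = params),
            class = "tms_target")
}

#' @export
print.tms_target <- function(x, ...) {
  cat("<tms_target> ", x$algorithm, " [", paste(round(x$world_mm, 2),
      collapse = ", "), "] mm  (", x$subject_id, " Day", x$day, x$phase,
      ")\n", sep = "")
  invisible(x)
}

#' Spearman distance matrix between voxel time series
#'
#' `d = 1 - rho` where `rho` is the Spearman rank correlation between each
#' pair of voxel time series; symmetric, zero diagonal, entries in \[0, 2\].
#'
#' @param ts voxel x time numeric matrix (>= 2 voxels, >= 3 time points).
#' @return voxel x voxel distance matrix.
#' @export
spearman_distance_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 2L) stop("need at least 2 voxels")
  if (ncol(ts) < 3L) stop("need at least 3 time points")
  sds <- apply(ts, 1, stats::sd)
  if (any(sds == 0))
    stop("constant voxel time series: rank correlation undefined (voxel ",
         which(sds == 0)[1], ")")
  d <- 1 - stats::cor(t(ts), method = "spearman")
  diag(d) <- 0
  d
}

#' Voxel adjacency matrix
#'
#' Logical n x n matrix: voxels i and j are adjacent under the given
#' connectivity (6 faces / 18 faces+edges / 26 faces+edges+corners).
#'
#' @param voxels n x 3 matrix of 1-based voxel indices.
#' @param connectivity 6, 18 or 26.
#' @return logical n x n matrix with `FALSE` diagonal.
#' @export
voxel_adjacency <- function(voxels, connectivity = 26) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("'connectivity' must be 6, 18 or 26")
  dx <- abs(outer(voxels[, 1], voxels[, 1], "-"))
  dy <- abs(outer(voxels[, 2], voxels[, 2], "-"))
  dz <- abs(outer(voxels[, 3], voxels[, 3], "-"))
  linf <- pmax(dx, pmax(dy, dz))
  l1 <- dx + dy + dz
  adj <- switch(as.character(connectivity),
                "6" = l1 == 1,
                "18" = linf == 1 & l1 <= 2,
                "26" = linf == 1)
  diag(adj) <- FALSE
  adj
}

#' Spatially constrained agglomerative clustering
#'
#' Bottom-up average-linkage clustering in which only spatially adjacent
#' clusters may merge: every voxel starts as its own cluster, and the
#' globally closest adjacent pair is merged iteratively until the minimum
#' adjacent-pair linkage distance exceeds `stop` (or a single cluster
#' remains). Two clusters count as adjacent iff any cross-pair of their
#' member voxels is adjacent; disconnected components therefore never merge.
#'
#' Ties (equal merge distances) are broken toward the pair whose clusters
#' contain the lowest linearized voxel indices, and final labels are
#' renumbered by each cluster's smallest member index, so the labeling is
#' invariant to voxel enumeration order.
#'
#' @param dist voxel x voxel distance matrix (e.g.
#'   [spearman_distance_matrix()]).
#' @param adjacency logical voxel x voxel adjacency matrix (e.g.
#'   [voxel_adjacency()]).
#' @param stop linkage-distance stopping threshold in (0, 2); default 0.5.
#' @return integer vector of cluster labels (1-based, contiguous).
#' @export
constrained_agglomerative_cluster <- function(dist, adjacency, stop = 0.5) {
  n <- nrow(dist)
  if (n == 0L) stop("empty mask: nothing to cluster")
  if (!identical(dim(adjacency), dim(dist)))
    stop("'adjacency' and 'dist' dimensions differ")
  if (!(stop > 0 && stop < 2)) stop("'stop' must be in (0, 2)")
  if (n == 1L) return(1L)
  D <- as.matrix(dist)
  A <- adjacency | t(adjacency)
  diag(A) <- FALSE
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  minvox <- seq_len(n)          # smallest original voxel index per cluster
  members <- as.list(seq_len(n))
  DA <- D
  DA[!A] <- Inf
  diag(DA) <- Inf
  repeat {
    dmin <- min(DA)
    if (!is.finite(dmin) || dmin > stop) break
    cand <- which(DA == dmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break: lexicographically smallest (minvox_i, minvox_j)
    key1 <- pmin(minvox[cand[, 1]], minvox[cand[, 2]])
    key2 <- pmax(minvox[cand[, 1]], minvox[cand[, 2]])
    pick <- order(key1, key2)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    if (minvox[j] < minvox[i]) { tmp <- i; i <- j; j <- tmp }
    # average-linkage update of cluster i <- i U j
    ni <- size[i]; nj <- size[j]
    upd <- (ni * D[i, ] + nj * D[j, ]) / (ni + nj)
    D[i, ] <- upd; D[, i] <- upd
    A[i, ] <- A[i, ] | A[j, ]; A[, i] <- A[i, ]
    size[i] <- ni + nj
    minvox[i] <- min(minvox[i], minvox[j])
    members[[i]] <- c(members[[i]], members[[j]])
    active[j] <- FALSE
    A[j, ] <- FALSE; A[, j] <- FALSE
    A[i, i] <- FALSE
    DA[i, ] <- ifelse(A[i, ], D[i, ], Inf)
    DA[, i] <- DA[i, ]
    DA[j, ] <- Inf; DA[, j] <- Inf
    DA[i, i] <- Inf
    if (sum(active) == 1L) break
  }
  labels <- integer(n)
  ids <- which(active)
  ids <- ids[order(minvox[ids])]
  for (k in seq_along(ids)) labels[members[[ids[k]]]] <- k
  labels
}

#' Subunit summaries for a clustering
#'
#' For each cluster ("subunit"): the elementwise median time course across
#' member voxels, the representative voxel (the member whose series has the
#' highest Pearson correlation with that median course), the voxel count,
#' and the spatial concentration (voxel count divided by the mean pairwise
#' Euclidean world-mm distance among members; defined as 0 for singletons).
#'
#' @param ts voxel x time matrix over the mask voxels.
#' @param labeling integer cluster labels from
#'   [constrained_agglomerative_cluster()].
#' @param voxels n x 3 matrix of the mask's voxel indices (same order as
#'   `ts` rows).
#' @param geom the [volume_geometry()].
#' @param stop the stopping threshold used (stored for provenance).
#' @return an object of class `subunit_set`: a list with `subunits` (each
#'   holding `voxel_rows`, `median_timecourse`, `representative_voxel`,
#'   `representative_series`, `representative_world`, `size`,
#'   `concentration`), plus `labeling`, `voxels`, `geometry`.
#' @export
subunit_summary <- function(ts, labeling, voxels, geom, stop = 0.5) {
  ts <- as.matrix(ts)
  if (nrow(ts) != length(labeling))
    stop("'labeling' length does not match the number of voxels")
  world <- voxel_to_world(voxels, geom)
  subunits <- lapply(sort(unique(labeling)), function(lab) {
    rows <- which(labeling == lab)
    sub_ts <- ts[rows, , drop = FALSE]
    med <- apply(sub_ts, 2, stats::median)
    if (length(rows) == 1L) {
      rep_row <- rows
    } else {
      cors <- suppressWarnings(as.vector(stats::cor(t(sub_ts), med)))
      cors[is.na(cors)] <- -Inf
      rep_row <- rows[which.max(cors)]
    }
    conc <- if (length(rows) < 2L) 0 else {
      pw <- stats::dist(world[rows, , drop = FALSE])
      length(rows) / mean(pw)
    }
    list(voxel_rows = rows,
         median_timecourse = med,
         representative_voxel = voxels[rep_row, ],
         representative_series = ts[rep_row, ],
         representative_world = world[rep_row, ],
         size = length(rows),
         concentration = conc)
  })
  structure(list(subunits = subunits, labeling = labeling, voxels = voxels,
                 geometry = geom, stop_threshold = stop),
            class = "subunit_set")
}

#' @export
print.subunit_set <- function(x, ...) {
  sizes <- vapply(x$subunits, `[[`, integer(1), "size")
  cat("<subunit_set> ", length(sizes), " subunits over ", sum(sizes),
      " voxels (sizes ", paste(utils::head(sort(sizes, decreasing = TRUE), 5),
      collapse = ", "), if (length(sizes) > 5) ", ...", ")\n", sep = "")
  invisible(x)
}

#' Cluster a masked region into subunits
#'
#' Convenience wrapper: extracts the mask's voxel time series, builds the
#' Spearman distance matrix and spatial adjacency, runs the constrained
#' agglomeration and summarizes the result.
#'
#' @param run a preprocessed [bold_run()].
#' @param mask a [binary_mask()].
#' @param stop linkage stopping threshold (default 0.5).
#' @param connectivity spatial adjacency rule, 6/18/26 (default 26).
#' @return a [subunit_summary()] `subunit_set`.
#' @export
hca_subunits <- function(run, mask, stop = 0.5, connectivity = 26) {
  vox <- mask_voxel_matrix(mask)
  ts <- t(mask_timeseries(run, mask))  # voxel x time
  d <- spearman_distance_matrix(ts)
  adj <- voxel_adjacency(vox, connectivity)
  labels <- constrained_agglomerative_cluster(d, adj, stop)
  subunit_summary(ts, labels, vox, mask$geometry, stop)
}

#' Three-parameter composite scoring of DLPFC subunits
#'
#' For each DLPFC subunit i and sgACC subunit j, the Pearson correlation
#' `r_ij` between their representative-voxel time series is computed. Each
#' DLPFC subunit is then described by (1) the sum of `r_ij` weighted by the
#' sgACC subunit voxel counts, (2) its spatial concentration, and (3) its
#' voxel count. The three parameters are z-scored across DLPFC subunits
#' (a zero-variance column z-scores to all zeros) and summed into the
#' composite score.
#'
#' @param dlpfc a `subunit_set` for the DLPFC mask (needs >= 2 subunits).
#' @param sgacc a `subunit_set` for the sgACC mask.
#' @return data.frame with one row per DLPFC subunit: `subunit_id`,
#'   `weighted_corr_sum`, `concentration`, `size`, `z_weighted`, `z_conc`,
#'   `z_size`, `composite`.
#' @export
score_subunits <- function(dlpfc, sgacc) {
  nd <- length(dlpfc$subunits)
  if (nd < 2L)
    stop("need >= 2 DLPFC subunits to z-score parameters; check the mask ",
         "and stopping threshold")
  sg_series <- vapply(sgacc$subunits, `[[`, numeric(length(
    sgacc$subunits[[1]]$representative_series)), "representative_series")
  sg_sizes <- vapply(sgacc$subunits, `[[`, integer(1), "size")
  rows <- lapply(seq_len(nd), function(i) {
    su <- dlpfc$subunits[[i]]
    r <- suppressWarnings(as.vector(stats::cor(sg_series,
                                               su$representative_series)))
    r[is.na(r)] <- 0
    data.frame(subunit_id = i,
               weighted_corr_sum = sum(r * sg_sizes),
               concentration = su$concentration,
               size = su$size)
  })
  out <- do.call(rbind, rows)
  out$z_weighted <- zscore_or_zero(out$weighted_corr_sum)
  out$z_conc <- zscore_or_zero(out$concentration)
  out$z_size <- zscore_or_zero(out$size)
  out$composite <- out$z_weighted + out$z_conc + out$z_size
  out
}

zscore_or_zero <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
}

#' Hierarchical-clustering target derivation
#'
#' Full HCA pipeline for one preprocessed run: cluster the DLPFC and sgACC
#' masks into subunits, score the DLPFC subunits in the three-parameter
#' space, and return the representative voxel of the subunit with the
#' highest composite z-score (ties broken toward the lowest subunit id) as
#' the stimulation target.
#'
#' @param run a preprocessed [bold_run()].
#' @param dlpfc_mask,sgacc_mask non-empty [binary_mask()]s.
#' @param stop linkage stopping threshold (default 0.5).
#' @param connectivity spatial adjacency rule (default 26).
#' @return a [tms_target()] (the score table is attached as attribute
#'   `"scores"`).
#' @export
hca_target <- function(run, dlpfc_mask, sgacc_mask, stop = 0.5,
                       connectivity = 26) {
  dl <- hca_subunits(run, dlpfc_mask, stop, connectivity)
  sg <- hca_subunits(run, sgacc_mask, stop, connectivity)
  if (length(dl$subunits) == 1L) {
    # degenerate parcellation (e.g. an overwhelming shared signal): the
    # sole subunit is trivially the argmax and scoring is undefined
    warning("DLPFC clustered into a single subunit at stop = ", stop,
            "; composite scoring skipped")
    sc <- NULL
    win <- 1L
  } else {
    sc <- score_subunits(dl, sg)
    win <- sc$subunit_id[which.max(sc$composite)]
  }
  tgt <- tms_target(dl$subunits[[win]]$representative_world, "HCA",
                    subject_id = run$subject_id, day = run$day,
                    phase = run$phase,
                    params = list(stop = stop, connectivity = connectivity))
  attr(tgt, "scores") <- sc
  attr(tgt, "winning_subunit") <- win
  tgt
}
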