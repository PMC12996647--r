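#' 3-D Euclidean distance between two targets
#'
#' @param a,b mm triples or [tms_target()]s.
#' @return distance in mm.
#' @export
euclidean_distance <- function(a, b) {
  a <- target_coords(a); b <- target_coords(b)
  sqrt(sum((a - b)^2))
}

target_coords <- function(x) {
  if (inherits(x, "tms_target")) x$world_mm else as.numeric(x)
}

#' Four-run target set for one subject
#'
#' Bundles the targets derived from the four runs (day 1/2 x phase LR/RL)
#' of one subject into a `target_quad`.
#'
#' @param day1_lr,day1_rl,day2_lr,day2_rl mm triples or [tms_target()]s.
#' @param subject_id subject identifier.
#' @return an object of class `target_quad`: a named list of four mm
#'   triples (`Day1LR`, `Day1RL`, `Day2LR`, `Day2RL`).
#' @export
target_quad <- function(day1_lr, day1_rl, day2_lr, day2_rl,
                        subject_id = NA_character_) {
  q <- lapply(list(Day1LR = day1_lr, Day1RL = day1_rl,
                   Day2LR = day2_lr, Day2RL = day2_rl), target_coords)
  for (t in q) if (length(t) != 3L || !all(is.finite(t)))
    stop("each target must be a finite mm triple")
  structure(c(q, list(subject_id = subject_id)), class = "target_quad")
}

quad_matrix <- function(quad) {
  rbind(Day1LR = quad$Day1LR, Day1RL = quad$Day1RL,
        Day2LR = quad$Day2LR, Day2RL = quad$Day2RL)
}

#' Distance indices decomposing test-retest variability
#'
#' From the four run targets of one subject:
#' \describe{
#'   \item{intra_dd}{(d(Day1LR, Day1RL) + d(Day2LR, Day2RL)) / 2 — same-day
#'     runs.}
#'   \item{inter_dd}{(d(Day1LR, Day2RL) + d(Day1RL, Day2LR)) / 2 —
#'     different-day, different-phase runs.}
#'   \item{intra_pd}{(d(Day1LR, Day2LR) + d(Day1RL, Day2RL)) / 2 — same
#'     phase encoding across days.}
#'   \item{inter_pd}{identical to `inter_dd` by definition (the same two
#'     pairs define both).}
#'   \item{six_pair_mean}{mean distance over all 6 run pairs.}
#' }
#'
#' @param quad a [target_quad()].
#' @return a list of class `distance_indices`.
#' @export
distance_indices <- function(quad) {
  m <- quad_matrix(quad)
  d <- function(a, b) sqrt(sum((m[a, ] - m[b, ])^2))
  intra_dd <- (d("Day1LR", "Day1RL") + d("Day2LR", "Day2RL")) / 2
  inter_dd <- (d("Day1LR", "Day2RL") + d("Day1RL", "Day2LR")) / 2
  intra_pd <- (d("Day1LR", "Day2LR") + d("Day1RL", "Day2RL")) / 2
  pairs <- utils::combn(rownames(m), 2)
  six <- mean(apply(pairs, 2, function(p) d(p[1], p[2])))
  structure(list(intra_dd = intra_dd, inter_dd = inter_dd,
                 intra_pd = intra_pd, inter_pd = inter_dd,
                 six_pair_mean = six, subject_id = quad$subject_id),
            class = "distance_indices")
}

#' @export
print.distance_indices <- function(x, ...) {
  cat("<distance_indices> IntraDD ", round(x$intra_dd, 2), " | InterDD ",
      round(x$inter_dd, 2), " | IntraPD ", round(x$intra_pd, 2),
      " | InterPD ", round(x$inter_pd, 2), " | 6-pair mean ",
      round(x$six_pair_mean, 2), " mm\n", sep = "")
  invisible(x)
}

#' Intra-individual variability report
#'
#' Centroid of the four run targets, the sample SD (n - 1) of the four
#' run-to-centroid 3-D distances, and the per-axis coordinate SDs.
#'
#' @param quad a [target_quad()].
#' @return a list of class `variability_report` with `centroid`,
#'   `sd_distance`, `sd_x`, `sd_y`, `sd_z`.
#' @export
variability_report <- function(quad) {
  m <- quad_matrix(quad)
  centroid <- colMeans(m)
  dists <- sqrt(rowSums(sweep(m, 2, centroid)^2))
  structure(list(centroid = centroid,
                 sd_distance = stats::sd(dists),
                 sd_x = stats::sd(m[, 1]),
                 sd_y = stats::sd(m[, 2]),
                 sd_z = stats::sd(m[, 3]),
                 subject_id = quad$subject_id),
            class = "variability_report")
}

#' Individual discriminability ratios
#'
#' For each subject: the intra-individual distance (mean over the 6
#' within-subject run pairs), the inter-individual distance (mean Euclidean
#' distance between targets of matching (day, phase) runs over all other
#' subjects), and their ratio inter / intra. A subject with perfectly
#' reproducible targets (intra = 0) is flagged and reported with ratio
#' `Inf`.
#'
#' @param quads list of [target_quad()]s (>= 2 subjects).
#' @return data.frame with columns `subject_id`, `intra_mean`, `inter_mean`,
#'   `ratio`, `degenerate`.
#' @export
discriminability_ratios <- function(quads) {
  if (length(quads) < 2L) stop("need at least 2 subjects")
  mats <- lapply(quads, quad_matrix)
  n <- length(mats)
  runs <- rownames(mats[[1]])
  out <- lapply(seq_len(n), function(s) {
    m <- mats[[s]]
    intra <- mean(stats::dist(m)[1:6])
    inter_d <- unlist(lapply(setdiff(seq_len(n), s), function(s2)
      sqrt(rowSums((m[runs, ] - mats[[s2]][runs, ])^2))))
    inter <- mean(inter_d)
    degenerate <- intra == 0
    data.frame(subject_id = quads[[s]]$subject_id %||% paste0("sub", s),
               intra_mean = intra, inter_mean = inter,
               ratio = if (degenerate) Inf else inter / intra,
               degenerate = degenerate)
  })
  res <- do.call(rbind, out)
  if (any(res$degenerate))
    warning("subject(s) with zero intra-individual distance: ratio ",
            "reported as Inf")
  res
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Temporal signal-to-noise ratio within a mask
#'
#' Mean over mask voxels of (temporal mean / temporal SD); voxels with zero
#' temporal SD are excluded with a warning.
#'
#' @param run a [bold_run()] (>= 2 time points).
#' @param mask a [binary_mask()].
#' @return scalar tSNR.
#' @export
tsnr <- function(run, mask) {
  ts <- mask_timeseries(run, mask)  # nt x nvox
  mu <- colMeans(ts)
  sdv <- apply(ts, 2, stats::sd)
  bad <- sdv == 0
  if (any(bad)) {
    warning(sum(bad), " zero-variance voxel(s) excluded from tSNR")
    if (all(bad)) stop("all mask voxels have zero temporal SD")
  }
  mean(mu[!bad] / sdv[!bad])
}

#' Write / read derived targets as CSV
#'
#' Columns: subject, algorithm, day, phase, x_mm, y_mm, z_mm, params (JSON).
#'
#' @param targets list of [tms_target()]s.
#' @param path CSV path.
#' @return (`targets_to_csv`) the data.frame written, invisibly;
#'   (`read_targets`) a data.frame.
#' @export
targets_to_csv <- function(targets, path) {
  df <- do.call(rbind, lapply(targets, function(t)
    data.frame(subject = t$subject_id, algorithm = t$algorithm,
               day = t$day, phase = t$phase,
               x_mm = t$world_mm[1], y_mm = t$world_mm[2],
               z_mm = t$world_mm[3],
               params = as.character(jsonlite::toJSON(t$params,
                                                      auto_unbox = TRUE)))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @rdname targets_to_csv
#' @export
read_targets <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Per-subject target quads from a targets table
#'
#' @param df data.frame as produced by [targets_to_csv()] (one algorithm).
#' @return named list of [target_quad()]s.
#' @export
quads_from_table <- function(df) {
  subjects <- unique(df$subject)
  out <- lapply(subjects, function(s) {
    d <- df[df$subject == s, ]
    pick <- function(day, phase) {
      r <- d[d$day == day & d$phase == phase, ]
      if (nrow(r) != 1L) stop("subject ", s, " is missing run Day", day, phase)
      c(r$x_mm, r$y_mm, r$z_mm)
    }
    target_quad(pick(1, "LR"), pick(1, "RL"), pick(2, "LR"), pick(2, "RL"),
                subject_id = s)
  })
  names(out) <- subjects
  out
}
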