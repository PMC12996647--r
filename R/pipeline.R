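#' End-to-end targeting pipeline over a cohort
#'
#' Preprocesses every run (fixed order: smoothing, nuisance regression with
#' motion + derivatives + CompCor and optionally the global signal,
#' band-pass), builds the population weight map from per-run sgACC
#' connectivity maps, derives RSA and HCA targets for every run, and
#' computes the reliability statistics (distance indices, variability
#' reports, discriminability ratios) plus a permutation comparison of the
#' two algorithms' six-pair mean distances.
#'
#' @param cohort a cohort from [simulate_cohort()] (or [read_cohort()]).
#' @param out_dir optional output directory; when given, per-run targets
#'   CSV, a reliability report CSV and a statistics JSON are written there.
#' @param fwhm smoothing FWHM mm (`NULL` skips; default 5).
#' @param gsr apply global signal regression (default `FALSE`).
#' @param fraction RSA retained fraction (default 0.5).
#' @param stop HCA linkage stopping threshold (default 0.5).
#' @param connectivity adjacency/contiguity rule (default 26).
#' @param compcor_k CompCor components (default 5); `NULL` skips CompCor.
#' @param use_motion include motion confounds when available.
#' @param truncate_nt keep only the first N time points of every run
#'   (data-length robustness check); `NULL` keeps all.
#' @param low,high band-pass edges in Hz.
#' @param n_iter permutation iterations for the RSA-vs-HCA comparison.
#' @param seed integer seed for the permutation test.
#' @return list with `targets` (data.frame), `weight_map`, `indices`
#'   (per subject x algorithm distance indices), `variability`,
#'   `discriminability`, `comparison` (permutation result RSA vs HCA on
#'   six-pair mean), and `config`.
#' @export
run_pipeline <- function(cohort, out_dir = NULL, fwhm = 5, gsr = FALSE,
                         fraction = 0.5, stop = 0.5, connectivity = 26,
                         compcor_k = 5, use_motion = TRUE,
                         truncate_nt = NULL, low = 0.01, high = 0.1,
                         n_iter = 2000, seed = 1) {
  masks <- cohort$masks
  wm_csf <- binary_mask(masks$wm$data | masks$csf$data, masks$geometry,
                        name = "wm_csf")
  config <- list(fwhm = fwhm, gsr = gsr, fraction = fraction, stop = stop,
                 connectivity = connectivity, compcor_k = compcor_k,
                 truncate_nt = truncate_nt, low = low, high = high,
                 n_iter = n_iter, seed = seed)

  pre <- lapply(cohort$subjects, function(s) {
    lapply(names(s$runs), function(rn) {
      run <- s$runs[[rn]]
      if (!is.null(truncate_nt))
        run$data <- run$data[, , , seq_len(min(truncate_nt,
                                               dim(run$data)[4])), drop = FALSE]
      preprocess_run(run, fwhm = fwhm,
                     motion = if (use_motion) s$motion[[rn]][
                       seq_len(dim(run$data)[4]), , drop = FALSE],
                     wm_csf_mask = if (!is.null(compcor_k)) wm_csf,
                     compcor_k = compcor_k, gsr = gsr,
                     brain_mask = masks$brain, low = low, high = high)
    })
  })

  fc_maps <- unlist(lapply(pre, function(runs)
    lapply(runs, sgacc_fc_map, sgacc_mask = masks$sgacc,
           brain_mask = masks$brain)), recursive = FALSE)
  w <- group_weight_map(fc_maps)

  targets <- list()
  for (si in seq_along(pre)) {
    for (run in pre[[si]]) {
      targets[[length(targets) + 1L]] <-
        rsa_target(run, w, masks$dlpfc, masks$brain, fraction = fraction,
                   connectivity = connectivity)
      targets[[length(targets) + 1L]] <-
        hca_target(run, masks$dlpfc, masks$sgacc, stop = stop,
                   connectivity = connectivity)
    }
    pre[[si]] <- list()  # release this subject's preprocessed volumes
  }
  tdf <- do.call(rbind, lapply(targets, function(t)
    data.frame(subject = t$subject_id, algorithm = t$algorithm,
               day = t$day, phase = t$phase, x_mm = t$world_mm[1],
               y_mm = t$world_mm[2], z_mm = t$world_mm[3])))

  res <- list(targets = tdf, weight_map = w, config = config)
  if (all(c("LR", "RL") %in% tdf$phase) && all(c(1, 2) %in% tdf$day)) {
    quads <- list(RSA = quads_from_table(tdf[tdf$algorithm == "RSA", ]),
                  HCA = quads_from_table(tdf[tdf$algorithm == "HCA", ]))
    res$indices <- do.call(rbind, lapply(names(quads), function(alg)
      do.call(rbind, lapply(quads[[alg]], function(q) {
        di <- distance_indices(q)
        data.frame(subject = q$subject_id, algorithm = alg,
                   intra_dd = di$intra_dd, inter_dd = di$inter_dd,
                   intra_pd = di$intra_pd, inter_pd = di$inter_pd,
                   six_pair_mean = di$six_pair_mean)
      }))))
    res$variability <- do.call(rbind, lapply(names(quads), function(alg)
      do.call(rbind, lapply(quads[[alg]], function(q) {
        vr <- variability_report(q)
        data.frame(subject = q$subject_id, algorithm = alg,
                   sd_distance = vr$sd_distance, sd_x = vr$sd_x,
                   sd_y = vr$sd_y, sd_z = vr$sd_z)
      }))))
    if (length(quads$RSA) >= 2) {
      res$discriminability <-
        do.call(rbind, lapply(names(quads), function(alg) {
          d <- discriminability_ratios(quads[[alg]])
          d$algorithm <- alg
          d
        }))
      hca_six <- res$indices$six_pair_mean[res$indices$algorithm == "HCA"]
      rsa_six <- res$indices$six_pair_mean[res$indices$algorithm == "RSA"]
      res$comparison <- paired_permutation_test(hca_six, rsa_six,
                                                n_iter = n_iter, seed = seed)
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tdf, file.path(out_dir, "targets.csv"),
                     row.names = FALSE)
    if (!is.null(res$indices))
      utils::write.csv(res$indices, file.path(out_dir, "reliability.csv"),
                       row.names = FALSE)
    stats_out <- list(config = config)
    if (!is.null(res$comparison))
      stats_out$hca_vs_rsa_six_pair <- list(
        observed = res$comparison$observed,
        p_value = res$comparison$p_value,
        n_iter = res$comparison$n_iter, seed = res$comparison$seed)
    jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return a cohort list usable by [run_pipeline()].
#' @export
read_cohort <- function(dir) {
  mdir <- file.path(dir, "masks")
  masks <- list(geometry = NULL)
  for (nm in c("brain", "dlpfc", "target_blob", "sgacc", "wm", "csf",
               "gray_matter")) {
    f <- file.path(mdir, paste0(nm, ".nii.gz"))
    if (file.exists(f)) masks[[nm]] <- read_volume(f, as = "mask")
  }
  masks$geometry <- masks$brain$geometry
  subs <- list.files(dir, pattern = "^sub-", full.names = TRUE)
  subjects <- lapply(subs, function(sd) {
    bolds <- list.files(file.path(sd, "func"), pattern = "_bold\\.nii(\\.gz)?$",
                        full.names = TRUE)
    runs <- lapply(bolds, read_volume)
    names(runs) <- vapply(runs, function(r) paste0("Day", r$day, r$phase), "")
    motion <- lapply(sub("_bold\\.nii(\\.gz)?$", "_confounds.tsv", bolds),
                     function(f) if (file.exists(f))
                       as.matrix(utils::read.delim(f)) else NULL)
    names(motion) <- names(runs)
    list(runs = runs, motion = motion)
  })
  names(subjects) <- basename(subs)
  out <- list(subjects = subjects, masks = masks)
  sf <- file.path(dir, "scores.csv")
  if (file.exists(sf)) out$scores <- utils::read.csv(sf)
  out
}
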