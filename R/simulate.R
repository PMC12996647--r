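#' Synthetic cohort specification
#'
#' Parameters of the synthetic resting-state generator. Each subject gets
#' `runs_per_subject` runs laid out as (day, phase) in {1,2} x {LR, RL}; a
#' latent band-limited (0.01-0.1 Hz) "sgACC" signal drives the sgACC-mask
#' voxels with unit coupling, a planted DLPFC blob with negative coupling
#' (`coupling_target`, perturbed per subject by `coupling_subject_sd`),
#' the remaining DLPFC voxels with heterogeneous couplings
#' (`coupling_background_sd`), and the rest of the brain weakly
#' (`coupling_other_sd`). The background DLPFC is additionally organized
#' into contiguous functional parcels (Voronoi cells of about
#' `parcel_size` voxels, fixed per subject), each driven by its own
#' band-limited subject-level latent of amplitude `parcel_amp` — the
#' voxel-wise heterogeneity the clustering algorithm exploits. The latent
#' signals are subject traits; only the global component, the day jitter
#' and the white noise vary between runs. A band-limited shared ("global") component of
#' amplitude `global_amp` is added to every gray-matter voxel with
#' loadings drawn per run from \[0.5, 1.5\]; WM/CSF carry none, so it
#' evades aCompCor and is removable only by GSR. Couplings are jittered
#' per acquisition day by `day_effect_sd`, and white voxel noise has SD
#' `run_noise_sd`. Symptom
#' scores are linear in the model-implied target-sgACC connectivity.
#'
#' @param n_subjects number of subjects (default 5).
#' @param runs_per_subject 4 (the 2 x 2 day/phase grid) or fewer.
#' @param dims grid size (default 24^3).
#' @param voxel_size voxel edge in mm (default 2).
#' @param tr repetition time in s (default 0.72).
#' @param nt time points per run (default 300, >= 64).
#' @param target_center planted blob centre, world mm.
#' @param target_radius planted blob radius, mm.
#' @param coupling_target blob coupling to the latent sgACC signal
#'   (negative; default -0.8).
#' @param coupling_subject_sd between-subject SD of the blob coupling.
#' @param coupling_background_sd SD of background DLPFC couplings.
#' @param coupling_other_sd SD of non-DLPFC brain couplings.
#' @param parcel_size target mean voxel count of background DLPFC parcels.
#' @param parcel_amp amplitude of the per-parcel latent signals.
#' @param global_amp amplitude of the shared global component.
#' @param run_noise_sd white voxel-noise SD.
#' @param day_effect_sd per-day coupling jitter SD.
#' @param baseline mean signal level inside the brain (gives realistic
#'   tSNR).
#' @param symptom_slope slope of score on target-sgACC FC (default 2).
#' @param symptom_noise_sd residual score SD.
#' @param seed mandatory integer master seed.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 5, runs_per_subject = 4,
                        dims = c(24, 24, 24), voxel_size = 2, tr = 0.72,
                        nt = 300, target_center = c(-12, 8, 10),
                        target_radius = 5.5, coupling_target = -0.8,
                        coupling_subject_sd = 0.1,
                        coupling_background_sd = 0.15,
                        coupling_other_sd = 0.05, parcel_size = 12,
                        parcel_amp = 1, global_amp = 0.5,
                        run_noise_sd = 0.6, day_effect_sd = 0.05,
                        baseline = 100, symptom_slope = 2,
                        symptom_noise_sd = 1, seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  if (nt < 64) stop("'nt' must be >= 64 (band-limited latent signals)")
  spec <- list(n_subjects = as.integer(n_subjects),
               runs_per_subject = as.integer(runs_per_subject),
               dims = as.integer(dims), voxel_size = voxel_size, tr = tr,
               nt = as.integer(nt), target_center = target_center,
               target_radius = target_radius,
               coupling_target = coupling_target,
               coupling_subject_sd = coupling_subject_sd,
               coupling_background_sd = coupling_background_sd,
               coupling_other_sd = coupling_other_sd,
               parcel_size = parcel_size, parcel_amp = parcel_amp,
               global_amp = global_amp, run_noise_sd = run_noise_sd,
               day_effect_sd = day_effect_sd, baseline = baseline,
               symptom_slope = symptom_slope,
               symptom_noise_sd = symptom_noise_sd,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  masks <- synthetic_masks(spec)
  if (any(masks$target_blob$data & !masks$dlpfc$data))
    stop("planted target blob must lie inside the synthetic DLPFC mask")
  spec
}

#' Synthetic masks (geometric primitives on the cohort grid)
#'
#' Brain, DLPFC search region, planted target blob, sgACC seed, white
#' matter, CSF and gray matter, all spheres on the spec's grid. The layout
#' mimics a left-prefrontal search region and a deep medial seed at the
#' scale of the synthetic volume.
#'
#' @param spec a [cohort_spec()].
#' @return named list of [binary_mask()]s plus the shared
#'   [volume_geometry()].
#' @export
synthetic_masks <- function(spec) {
  geom <- volume_geometry(spec$dims,
                          voxel_size = rep(spec$voxel_size, 3))
  brain <- make_sphere_mask(c(0, 0, 0), 23.5, geom, name = "brain")
  dlpfc <- make_sphere_mask(c(-10, 6, 8), 9, geom, name = "dlpfc")
  blob <- make_sphere_mask(spec$target_center, spec$target_radius, geom,
                           name = "target_blob")
  sgacc <- make_sphere_mask(c(8, 6, -8), 5, geom, name = "sgacc")
  wm <- make_sphere_mask(c(10, -8, 4), 4, geom, name = "wm")
  csf <- make_sphere_mask(c(0, -12, -6), 3, geom, name = "csf")
  gm <- binary_mask(brain$data & !wm$data & !csf$data, geom,
                    name = "gray_matter")
  list(geometry = geom, brain = brain, dlpfc = dlpfc, target_blob = blob,
       sgacc = sgacc, wm = wm, csf = csf, gray_matter = gm)
}

# smooth positive spatial field, mean ~1, SD ~0.35: white noise smoothed
# with a 4-mm-sigma Gaussian (so the field varies within a ~2-cm search
# region), standardized, then shifted
smooth_loading_field <- function(dims, voxel_size) {
  f <- array(stats::rnorm(prod(dims)), dim = c(dims, 1L))
  for (ax in 1:3) {
    K <- gaussian_axis_matrix(dims[ax], 4 / voxel_size)
    f <- apply_along_axis(f, ax, K)
  }
  f <- (f - mean(f)) / stats::sd(f)
  pmax(1 + 0.35 * f[, , , 1], 0)
}

# white noise filtered into [low, high] Hz and rescaled to unit SD
band_limited_noise <- function(nt, tr, low = 0.01, high = 0.1) {
  x <- stats::rnorm(nt)
  freq <- seq_len(nt) - 1
  freq <- pmin(freq, nt - freq) / (nt * tr)
  keep <- freq >= low & freq <= high
  co <- stats::fft(x)
  co[!keep] <- 0
  y <- Re(stats::fft(co, inverse = TRUE)) / nt
  y / stats::sd(y)
}

subject_seed <- function(spec, subject_index) {
  as.integer((as.double(spec$seed) + 7919 * subject_index) %% 2147483647)
}

#' Simulate one subject's runs
#'
#' Generates the subject's four (or fewer) runs with planted connectivity
#' structure and the ground-truth record needed to verify any planted
#' quantity independently.
#'
#' @param spec a [cohort_spec()].
#' @param subject_index subject number (1-based); determines the
#'   subject-level RNG stream.
#' @return list with `runs` (list of [bold_run()]s), `motion` (per-run
#'   nt x 6 matrices), and `truth` (blob centroid in mm, per-voxel coupling
#'   array, subject-level blob coupling, global loadings, model-implied
#'   target-sgACC FC).
#' @export
simulate_subject <- function(spec, subject_index = 1) {
  masks <- synthetic_masks(spec)
  geom <- masks$geometry
  set.seed(subject_seed(spec, subject_index))
  nvox <- prod(spec$dims)
  brain_v <- as.vector(masks$brain$data)
  sg_v <- as.vector(masks$sgacc$data)
  dl_v <- as.vector(masks$dlpfc$data) & !sg_v
  blob_v <- as.vector(masks$target_blob$data) & !sg_v
  bg_v <- dl_v & !blob_v
  other_v <- brain_v & !dl_v & !sg_v

  c_s <- spec$coupling_target + spec$coupling_subject_sd * stats::rnorm(1)
  coup <- numeric(nvox)
  coup[sg_v] <- 1
  coup[blob_v] <- c_s
  coup[bg_v] <- stats::rnorm(sum(bg_v), 0, spec$coupling_background_sd)
  coup[other_v] <- stats::rnorm(sum(other_v), 0, spec$coupling_other_sd)
  # background DLPFC parcels: Voronoi cells (world mm) over random seed
  # voxels, fixed per subject
  bg_idx <- which(bg_v)
  n_parcel <- max(1L, round(length(bg_idx) / spec$parcel_size))
  bg_world <- voxel_to_world(arrayInd(bg_idx, spec$dims), geom)
  seeds <- sample(length(bg_idx), n_parcel)
  d2seed <- vapply(seeds, function(s)
    rowSums(sweep(bg_world, 2, bg_world[s, ])^2), numeric(length(bg_idx)))
  parcel_of <- max.col(-d2seed, ties.method = "first")
  # the shared "global" component is modelled as gray-matter-restricted
  # (neural): WM/CSF carry none, so aCompCor cannot remove it — only GSR can
  gm_v <- as.vector(masks$gray_matter$data)
  day_jitter <- matrix(0, nvox, 2)
  day_jitter[brain_v & !sg_v, ] <-
    stats::rnorm(2 * sum(brain_v & !sg_v), 0, spec$day_effect_sd)
  # subject-level latents: the sgACC signal and the parcel signals are
  # stable traits of the subject, re-observed in every run
  s <- band_limited_noise(spec$nt, spec$tr)
  u <- if (length(bg_idx)) vapply(seq_len(n_parcel), function(k)
    band_limited_noise(spec$nt, spec$tr), numeric(spec$nt))

  run_keys <- list(c(1L, "LR"), c(1L, "RL"), c(2L, "LR"), c(2L, "RL"))
  run_keys <- run_keys[seq_len(spec$runs_per_subject)]
  runs <- list(); motion <- list()
  for (k in seq_along(run_keys)) {
    day <- as.integer(run_keys[[k]][1]); phase <- run_keys[[k]][2]
    g <- band_limited_noise(spec$nt, spec$tr)
    # per-run global loadings: a smooth spatial field (mean 1) that
    # drifts between scans, making the shared component a test-retest
    # hazard rather than a fixed bias
    lambda <- as.vector(smooth_loading_field(spec$dims,
                                             spec$voxel_size)) * gm_v
    cr <- coup + day_jitter[, day]
    # nvox x nt = couplings o latent + global + white noise, inside brain
    dat <- outer(cr, s) + spec$global_amp * outer(lambda, g)
    if (spec$parcel_amp > 0 && length(bg_idx))
      dat[bg_idx, ] <- dat[bg_idx, ] +
        spec$parcel_amp * t(u[, parcel_of, drop = FALSE])
    if (spec$run_noise_sd > 0)
      dat[brain_v, ] <- dat[brain_v, ] +
        stats::rnorm(sum(brain_v) * spec$nt, 0, spec$run_noise_sd)
    dat[brain_v, ] <- dat[brain_v, ] + spec$baseline
    dat[!brain_v, ] <- 0
    runs[[k]] <- bold_run(array(dat, dim = c(spec$dims, spec$nt)), geom,
                          tr = spec$tr,
                          subject_id = sprintf("sub-%02d", subject_index),
                          day = day, phase = phase)
    mo <- apply(matrix(stats::rnorm(spec$nt * 6, 0, 0.02), ncol = 6), 2,
                cumsum)
    colnames(mo) <- c("trans_x", "trans_y", "trans_z",
                      "rot_x", "rot_y", "rot_z")
    motion[[k]] <- mo
  }
  names(runs) <- names(motion) <-
    vapply(run_keys, function(x) paste0("Day", x[1], x[2]), "")
  B <- sum(blob_v); G <- sum(sg_v); s2 <- spec$run_noise_sd^2
  fc_true <- c_s / sqrt((c_s^2 + s2 / max(B, 1)) * (1 + s2 / max(G, 1)))
  list(runs = runs, motion = motion, masks = masks,
       truth = list(blob_centroid = cluster_centroid(masks$target_blob),
                    coupling = array(coup, dim = spec$dims),
                    blob_coupling = c_s,
                    fc_true = fc_true))
}

#' Simulate a whole cohort
#'
#' @param spec a [cohort_spec()].
#' @return list with `subjects` (each as returned by [simulate_subject()]),
#'   `masks`, and the `spec`.
#' @export
simulate_cohort <- function(spec) {
  subjects <- lapply(seq_len(spec$n_subjects), function(i)
    simulate_subject(spec, i))
  names(subjects) <- sprintf("sub-%02d", seq_len(spec$n_subjects))
  list(subjects = subjects, masks = synthetic_masks(spec), spec = spec)
}

#' Simulate a cohort with symptom scores (full 4-D runs)
#'
#' As [simulate_cohort()], plus a score table: per subject the
#' model-implied ("noiseless couplings") target-sgACC connectivity is
#' computed, and the symptom score is
#' `intercept + symptom_slope * FC + 0.05 * (age - 37) + 0.5 * sex + noise`.
#' Ages are uniform on 19..55, sex is Bernoulli(0.5) coded 0/1.
#'
#' @param spec a [cohort_spec()].
#' @param score_intercept intercept of the score model (default 20).
#' @return list with `subjects`, `masks`, `spec`, and `scores` (data.frame
#'   `subject, score, age, sex, fc_true`).
#' @export
simulate_cohort_with_scores <- function(spec, score_intercept = 20) {
  cohort <- simulate_cohort(spec)
  set.seed(as.integer((as.double(spec$seed) + 104729) %% 2147483647))
  n <- spec$n_subjects
  fc <- vapply(cohort$subjects, function(s) s$truth$fc_true, numeric(1))
  age <- round(stats::runif(n, 19, 55))
  sex <- stats::rbinom(n, 1, 0.5)
  score <- score_intercept + spec$symptom_slope * fc +
    0.05 * (age - 37) + 0.5 * sex +
    stats::rnorm(n, 0, spec$symptom_noise_sd)
  cohort$scores <- data.frame(subject = names(cohort$subjects),
                              score = score, age = age, sex = sex,
                              fc_true = fc)
  cohort
}

#' Fast cohort-level FC generator for the symptom-association analysis
#'
#' Generates per-subject target-sgACC FC vectors directly at the cohort
#' level (no 4-D volumes): voxels of a planted "core" subregion of the
#' sgACC carry the subject's true connectivity plus measurement noise,
#' while the remaining sgACC voxels carry score-unrelated values of a
#' matched marginal spread. Scores follow the same linear model as
#' [simulate_cohort_with_scores()]. Setting `null = TRUE` breaks the
#' score-FC link (slope 0) while keeping everything else identical.
#'
#' @param spec a [cohort_spec()]; `n_subjects` is typically larger here
#'   (e.g. 60).
#' @param fc_noise_sd measurement noise SD on the core FC values
#'   (default 0.01).
#' @param core_radius radius (mm) of the planted core inside the sgACC
#'   (default 3).
#' @param null generate a null cohort (scores independent of FC).
#' @param score_intercept intercept of the score model.
#' @return list with `fc` (n_subjects x n_voxels), `scores` (data.frame),
#'   `sgacc` mask, `core_rows` (indices of planted voxels in mask order),
#'   and `truth` (per-subject FC).
#' @export
simulate_fc_cohort <- function(spec, fc_noise_sd = 0.01, core_radius = 3,
                               null = FALSE, score_intercept = 20) {
  masks <- synthetic_masks(spec)
  sg_vox <- mask_voxel_matrix(masks$sgacc)
  core <- make_sphere_mask(c(8, 6, -8), core_radius, masks$geometry,
                           name = "sgacc_core")
  core_lin <- which(as.vector(core$data))
  sg_lin <- which(as.vector(masks$sgacc$data))
  core_rows <- match(core_lin, sg_lin)
  if (anyNA(core_rows)) stop("planted core must lie inside the sgACC mask")
  set.seed(as.integer((as.double(spec$seed) + 15485863) %% 2147483647))
  n <- spec$n_subjects
  nv <- length(sg_lin)
  c_s <- spec$coupling_target + spec$coupling_subject_sd * stats::rnorm(n)
  fc_true <- c_s / sqrt(c_s^2 + spec$run_noise_sd^2)
  fc <- matrix(mean(fc_true) +
                 stats::rnorm(n * nv, 0, sqrt(stats::var(fc_true) +
                                                fc_noise_sd^2)),
               n, nv)
  fc[, core_rows] <- fc_true + stats::rnorm(n * length(core_rows), 0,
                                            fc_noise_sd)
  age <- round(stats::runif(n, 19, 55))
  sex <- stats::rbinom(n, 1, 0.5)
  slope <- if (null) 0 else spec$symptom_slope
  score <- score_intercept + slope * fc_true +
    0.05 * (age - 37) + 0.5 * sex + stats::rnorm(n, 0, spec$symptom_noise_sd)
  list(fc = fc,
       scores = data.frame(subject = sprintf("sub-%02d", seq_len(n)),
                           score = score, age = age, sex = sex),
       sgacc = masks$sgacc, core_rows = core_rows,
       truth = list(fc_true = fc_true, slope = slope))
}

#' Write a simulated cohort to disk
#'
#' Emits a BIDS-flavoured layout: `sub-XX/func/*.nii.gz` with JSON
#' sidecars, `masks/*.nii.gz`, `ground_truth.json`, and `scores.csv` when
#' scores are present.
#'
#' @param cohort result of [simulate_cohort()] or
#'   [simulate_cohort_with_scores()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mdir <- file.path(dir, "masks")
  dir.create(mdir, showWarnings = FALSE)
  for (nm in c("brain", "dlpfc", "target_blob", "sgacc", "wm", "csf",
               "gray_matter"))
    write_volume(cohort$masks[[nm]], file.path(mdir, paste0(nm, ".nii.gz")))
  truth <- list()
  for (sub in names(cohort$subjects)) {
    s <- cohort$subjects[[sub]]
    fdir <- file.path(dir, sub, "func")
    dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
    for (rn in names(s$runs)) {
      base <- file.path(fdir, paste0(sub, "_", rn, "_bold.nii.gz"))
      write_volume(s$runs[[rn]], base)
      utils::write.table(s$motion[[rn]],
                         file.path(fdir, paste0(sub, "_", rn,
                                                "_confounds.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    truth[[sub]] <- list(blob_centroid = s$truth$blob_centroid,
                         blob_coupling = s$truth$blob_coupling,
                         fc_true = s$truth$fc_true)
  }
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(cohort$scores))
    utils::write.csv(cohort$scores, file.path(dir, "scores.csv"),
                     row.names = FALSE)
  invisible(dir)
}
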