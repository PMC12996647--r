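#' BOLD run container
#'
#' One resting-state run: a 4-D array (x, y, z, time), its geometry, the
#' repetition time, and acquisition metadata (subject, day, phase-encoding
#' direction). Runs are labelled Day1LR / Day1RL / Day2LR / Day2RL in the
#' test-retest analyses.
#'
#' @param data numeric 4-D array (nx, ny, nz, nt), finite, nt >= 2.
#' @param geometry a [volume_geometry()] matching `dim(data)[1:3]`.
#' @param tr repetition time in seconds.
#' @param subject_id subject identifier string.
#' @param day acquisition day, 1 or 2.
#' @param phase phase-encoding direction, "LR" or "RL".
#' @return an object of class `bold_run`.
#' @export
bold_run <- function(data, geometry, tr, subject_id = "sub-01",
                     day = 1L, phase = "LR") {
  if (length(dim(data)) != 4L) stop("'data' must be a 4-D array")
  if (dim(data)[4] < 2L) stop("a BOLD run needs at least 2 time points")
  if (!all(is.finite(data))) stop("'data' must be finite")
  if (!identical(as.integer(dim(data)[1:3]), geometry$dims))
    stop("geometry dims do not match the data array")
  if (!is.numeric(tr) || tr <= 0) stop("'tr' must be a positive number")
  day <- as.integer(day)
  if (!day %in% c(1L, 2L)) stop("'day' must be 1 or 2")
  phase <- match.arg(phase, c("LR", "RL"))
  structure(list(data = data, geometry = geometry, tr = as.numeric(tr),
                 subject_id = as.character(subject_id), day = day,
                 phase = phase),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat("<bold_run> ", x$subject_id, " Day", x$day, x$phase, ": ",
      paste(dim(x$data), collapse = " x "), " (TR ", x$tr, " s)\n", sep = "")
  invisible(x)
}

n_timepoints <- function(run) dim(run$data)[4]

#' Binary mask and weight-map containers
#'
#' A `binary_mask` is a logical 3-D volume plus geometry (DLPFC / sgACC /
#' brain / tissue masks); a `weight_map` is a real-valued 3-D volume sharing
#' the same geometry contract (e.g. the population-based sgACC connectivity
#' weighting mask used by the seed-based algorithm).
#'
#' @param data logical (mask) or numeric (weight map) 3-D array.
#' @param geometry a [volume_geometry()].
#' @param name label used in messages and provenance.
#' @param require_nonempty error if the mask has no `TRUE` voxel (the default
#'   for analysis masks).
#' @return an object of class `binary_mask` or `weight_map`.
#' @export
binary_mask <- function(data, geometry, name = "mask",
                        require_nonempty = TRUE) {
  if (length(dim(data)) != 3L) stop("mask 'data' must be a 3-D array")
  if (!identical(as.integer(dim(data)), geometry$dims))
    stop("geometry dims do not match the mask array")
  if (is.numeric(data)) {
    if (!all(data %in% c(0, 1))) stop("numeric mask values must be 0/1")
    data <- array(data != 0, dim = dim(data))
  }
  if (!is.logical(data)) stop("mask 'data' must be logical or 0/1")
  if (anyNA(data)) stop("mask 'data' must not contain NA")
  if (require_nonempty && !any(data))
    stop("mask '", name, "' is empty")
  structure(list(data = data, geometry = geometry, name = as.character(name)),
            class = "binary_mask")
}

#' @rdname binary_mask
#' @export
weight_map <- function(data, geometry, name = "weights") {
  if (length(dim(data)) != 3L) stop("weight 'data' must be a 3-D array")
  if (!identical(as.integer(dim(data)), geometry$dims))
    stop("geometry dims do not match the weight array")
  if (any(is.infinite(data))) stop("weight values must be finite (NA allowed)")
  structure(list(data = data, geometry = geometry, name = as.character(name)),
            class = "weight_map")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> '", x$name, "': ", sum(x$data), " / ",
      prod(x$geometry$dims), " voxels\n", sep = "")
  invisible(x)
}

#' @export
print.weight_map <- function(x, ...) {
  rng <- range(x$data, na.rm = TRUE)
  cat("<weight_map> '", x$name, "': range [", signif(rng[1], 4), ", ",
      signif(rng[2], 4), "]\n", sep = "")
  invisible(x)
}

#' Mask accessors
#'
#' `mask_count()`: number of `TRUE` voxels. `mask_voxel_matrix()`: n x 3
#' matrix of their 1-based indices in column-major (linearized) order — the
#' canonical voxel enumeration used for tie-breaks throughout.
#' `mask_world_coords()`: their world-mm centre coordinates.
#' `mask_timeseries()`: the nt x n matrix of their time series in a run.
#'
#' @param mask a [binary_mask()].
#' @param run a [bold_run()] sharing the mask's geometry.
#' @name mask-accessors
NULL

#' @rdname mask-accessors
#' @export
mask_count <- function(mask) sum(mask$data)

#' @rdname mask-accessors
#' @export
mask_voxel_matrix <- function(mask) {
  which(mask$data, arr.ind = TRUE, useNames = FALSE)
}

#' @rdname mask-accessors
#' @export
mask_world_coords <- function(mask) {
  voxel_to_world(mask_voxel_matrix(mask), mask$geometry)
}

#' @rdname mask-accessors
#' @export
mask_timeseries <- function(run, mask) {
  stopifnot_same_geometry(run, mask)
  nt <- n_timepoints(run)
  m <- matrix(run$data, ncol = nt)[as.vector(mask$data), , drop = FALSE]
  t(m)
}
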