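#' Isotropic Gaussian spatial smoothing
#'
#' Convolves each volume of a run with an isotropic Gaussian of the given
#' full width at half maximum, sigma = fwhm / (2 * sqrt(2 * log(2))) mm,
#' converted to voxel units per axis. The kernel is truncated at 4 sigma and
#' renormalized at the volume boundary, so a constant volume is exactly
#' preserved.
#'
#' @param run a [bold_run()].
#' @param fwhm kernel FWHM in mm (> 0); the denoising default is 5 mm.
#' @return the smoothed [bold_run()].
#' @export
smooth_gaussian <- function(run, fwhm) {
  if (!is.numeric(fwhm) || length(fwhm) != 1L || fwhm <= 0)
    stop("'fwhm' must be a positive scalar (mm)")
  sigma_mm <- fwhm / (2 * sqrt(2 * log(2)))
  d <- dim(run$data)
  x <- run$data
  for (ax in 1:3) {
    K <- gaussian_axis_matrix(d[ax], sigma_mm / run$geometry$voxel_size[ax])
    x <- apply_along_axis(x, ax, K)
  }
  run$data <- x
  run
}

# n x n convolution matrix for one axis: truncated discrete Gaussian with
# rows renormalized to sum 1 (boundary renormalization)
gaussian_axis_matrix <- function(n, sigma_vox) {
  pos <- seq_len(n)
  D <- outer(pos, pos, function(i, j) (i - j)^2)
  K <- exp(-D / (2 * sigma_vox^2))
  K[sqrt(D) > max(1, ceiling(4 * sigma_vox))] <- 0
  K / rowSums(K)
}

# multiply a (nx, ny, nz, nt) array by matrix K along axis `ax`
apply_along_axis <- function(x, ax, K) {
  d <- dim(x)
  perm <- c(ax, setdiff(seq_along(d), ax))
  xp <- aperm(x, perm)
  m <- K %*% matrix(xp, nrow = d[ax])
  xp <- array(m, dim = d[perm])
  aperm(xp, order(perm))
}

#' Anatomical CompCor nuisance components
#'
#' Top-k principal-component time series of the demeaned voxel-by-time
#' matrix within a tissue mask (typically white matter + CSF), ordered by
#' explained variance. These enter the nuisance regression alongside motion
#' parameters.
#'
#' @param run a [bold_run()].
#' @param tissue_mask a [binary_mask()] with at least `k` voxels.
#' @param k number of components (default 5).
#' @return an nt x k matrix with columns `compcor_1..k`; the explained
#'   variance ratios are attached as attribute `"explained_variance"`.
#' @export
compcor_components <- function(run, tissue_mask, k = 5) {
  k <- as.integer(k)
  ts <- mask_timeseries(run, tissue_mask)  # nt x nvox
  nt <- nrow(ts)
  if (ncol(ts) < k) stop("tissue mask has fewer than k = ", k, " voxels")
  if (nt <= k) stop("need more than k = ", k, " time points")
  ts <- sweep(ts, 2, colMeans(ts))
  if (all(abs(ts) < 1e-12))
    stop("tissue signals are constant; CompCor components are undefined")
  sv <- svd(ts, nu = k, nv = 0)
  comps <- sv$u
  colnames(comps) <- paste0("compcor_", seq_len(k))
  attr(comps, "explained_variance") <- (sv$d^2 / sum(sv$d^2))[seq_len(k)]
  comps
}

#' Temporal derivatives of motion parameters
#'
#' Backward differences with a zero first row, preserving the number of time
#' points.
#'
#' @param confounds nt x k numeric matrix.
#' @return nt x k matrix of derivatives, columns suffixed `_deriv`.
#' @export
motion_derivatives <- function(confounds) {
  confounds <- as.matrix(confounds)
  d <- rbind(0, diff(confounds))
  colnames(d) <- paste0(colnames(confounds), "_deriv")
  d
}

#' Nuisance regression
#'
#' Removes an intercept plus the given confound columns from every voxel
#' time series by ordinary least squares; the residuals are exactly
#' orthogonal to each confound column.
#'
#' @param run a [bold_run()].
#' @param confounds nt x k numeric matrix (motion parameters, derivatives,
#'   CompCor components, optionally the global signal).
#' @return the residual [bold_run()].
#' @export
regress_nuisance <- function(run, confounds) {
  confounds <- as.matrix(confounds)
  nt <- n_timepoints(run)
  if (nrow(confounds) != nt)
    stop("confound rows (", nrow(confounds), ") do not match nt (", nt, ")")
  if (anyNA(confounds)) stop("confounds must not contain NA")
  X <- cbind(intercept = 1, confounds)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("confound design is rank-deficient; offending column(s): ",
         paste(dropped, collapse = ", "))
  }
  Y <- matrix(run$data, ncol = nt)  # nvox x nt
  res <- qr.resid(qx, t(Y))        # nt x nvox
  run$data <- array(t(res), dim = dim(run$data))
  run
}

#' Ideal band-pass filter
#'
#' Hard-cutoff Fourier filter: coefficients at frequencies outside
#' `[low, high]` Hz (including the DC term) are zeroed, so the output is
#' mean-free and in-band sinusoids pass essentially unchanged.
#'
#' @param run a [bold_run()].
#' @param low,high band edges in Hz; defaults 0.01 and 0.1. Requires
#'   `0 < low < high < ` Nyquist (`1 / (2 tr)`).
#' @return the filtered [bold_run()].
#' @export
bandpass <- function(run, low = 0.01, high = 0.1) {
  nt <- n_timepoints(run)
  nyq <- 1 / (2 * run$tr)
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (high >= nyq) stop("'high' must be below the Nyquist frequency ",
                        signif(nyq, 4), " Hz")
  freq <- seq_len(nt) - 1
  freq <- pmin(freq, nt - freq) / (nt * run$tr)
  keep <- freq >= low & freq <= high
  Y <- matrix(run$data, ncol = nt)          # nvox x nt
  co <- stats::mvfft(t(Y))                  # nt x nvox
  co[!keep, ] <- 0
  filt <- Re(stats::mvfft(co, inverse = TRUE)) / nt
  run$data <- array(t(filt), dim = dim(run$data))
  run
}

#' Global signal regression
#'
#' Computes the global signal as the mean time series over the brain mask
#' and removes it (plus an intercept) from every voxel by OLS. After GSR the
#' correlation of any voxel with the regressed global signal is numerically
#' zero and the recomputed global mean has (numerically) zero variance.
#'
#' @param run a [bold_run()].
#' @param brain_mask a non-empty [binary_mask()].
#' @return the residual [bold_run()].
#' @export
global_signal_regress <- function(run, brain_mask) {
  gs <- global_signal(run, brain_mask)
  if (stats::var(gs) < 1e-20) stop("global signal has zero variance")
  regress_nuisance(run, cbind(global_signal = gs))
}

#' @rdname global_signal_regress
#' @export
global_signal <- function(run, brain_mask) {
  rowMeans(mask_timeseries(run, brain_mask))
}

#' Full denoising pipeline for one run
#'
#' Fixed order: spatial smoothing, then nuisance regression (motion
#' parameters + derivatives + CompCor components, with the global signal as
#' an additional column of the same regression when `gsr = TRUE`), then
#' band-pass filtering.
#'
#' @param run a [bold_run()].
#' @param fwhm smoothing FWHM in mm; `NULL` skips smoothing.
#' @param motion optional nt x 6 motion-parameter matrix; temporal
#'   derivatives are added automatically.
#' @param wm_csf_mask optional tissue mask for CompCor.
#' @param compcor_k number of CompCor components (default 5).
#' @param gsr logical: include global signal regression (requires
#'   `brain_mask`).
#' @param brain_mask brain mask used for the global signal.
#' @param low,high band-pass edges in Hz; `NULL` for `low` skips filtering.
#' @return the preprocessed [bold_run()].
#' @export
preprocess_run <- function(run, fwhm = 5, motion = NULL, wm_csf_mask = NULL,
                           compcor_k = 5, gsr = FALSE, brain_mask = NULL,
                           low = 0.01, high = 0.1) {
  if (!is.null(fwhm)) run <- smooth_gaussian(run, fwhm)
  conf <- NULL
  if (!is.null(motion))
    conf <- cbind(motion, motion_derivatives(motion))
  if (!is.null(wm_csf_mask))
    conf <- cbind(conf, compcor_components(run, wm_csf_mask, compcor_k))
  if (gsr) {
    if (is.null(brain_mask)) stop("GSR requires a 'brain_mask'")
    conf <- cbind(conf, global_signal = global_signal(run, brain_mask))
  }
  if (!is.null(conf)) run <- regress_nuisance(run, conf)
  if (!is.null(low)) run <- bandpass(run, low, high)
  run
}
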