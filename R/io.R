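#' Read and write NIfTI-1 volumes
#'
#' `read_volume()` loads a 3-D or 4-D NIfTI-1 file; 4-D files become
#' [bold_run()] objects (run metadata taken from a JSON sidecar when present,
#' TR from the header otherwise), 3-D files become a [binary_mask()] or
#' [weight_map()] according to `as`. `write_volume()` writes any of these
#' back, masks as uint8, and emits the JSON sidecar
#' `{subject, day, phase, tr}` next to BOLD runs.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param as for 3-D files, `"mask"` or `"weights"`; ignored for 4-D files.
#' @param sidecar path to the JSON metadata sidecar; defaults to `path` with
#'   the NIfTI extension replaced by `.json`.
#' @return a `bold_run`, `binary_mask` or `weight_map`.
#' @export
read_volume <- function(path, as = c("mask", "weights"), sidecar = NULL) {
  as <- match.arg(as)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI file: ",
                                           path, " (", conditionMessage(e), ")"))
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (all(is.na(arr))) stop("volume is NaN-only: ", path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  nd <- length(dim(arr))
  geom <- volume_geometry(dim(arr)[1:3], affine = aff)
  if (nd == 4L) {
    meta <- list(subject = "sub-01", day = 1L, phase = "LR",
                 tr = RNifti::niftiHeader(img)$pixdim[5])
    if (is.null(sidecar)) sidecar <- sidecar_path(path)
    if (file.exists(sidecar)) {
      sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      meta[names(sc)] <- sc
    }
    if (!is.numeric(meta$tr) || meta$tr <= 0)
      stop("no usable TR in header or sidecar for ", path)
    bold_run(arr, geom, tr = meta$tr, subject_id = meta$subject,
             day = meta$day, phase = meta$phase)
  } else if (nd == 3L) {
    if (as == "mask") binary_mask(arr != 0, geom,
                                  name = sub("\\.nii(\\.gz)?$", "", basename(path)),
                                  require_nonempty = FALSE)
    else weight_map(arr, geom)
  } else {
    stop("expected a 3-D or 4-D NIfTI volume, got ", nd, " dimensions")
  }
}

#' @rdname read_volume
#' @param x a `bold_run`, `binary_mask` or `weight_map`.
#' @export
write_volume <- function(x, path) {
  UseMethod("write_volume")
}

#' @export
write_volume.bold_run <- function(x, path) {
  write_nifti_array(x$data, x$geometry, path, tr = x$tr, datatype = "double")
  jsonlite::write_json(list(subject = x$subject_id, day = x$day,
                            phase = x$phase, tr = x$tr),
                       sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' @export
write_volume.binary_mask <- function(x, path) {
  write_nifti_array(array(as.integer(x$data), dim = dim(x$data)),
                    x$geometry, path, datatype = "uint8")
  invisible(path)
}

#' @export
write_volume.weight_map <- function(x, path) {
  write_nifti_array(x$data, x$geometry, path, datatype = "double")
  invisible(path)
}

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

write_nifti_array <- function(arr, geom, path, tr = 1, datatype = "double") {
  aff <- geom$affine
  hdr <- list(pixdim = c(-1, geom$voxel_size, tr, 0, 0, 0),
              sform_code = 2L, qform_code = 0L,
              srow_x = aff[1, ], srow_y = aff[2, ], srow_z = aff[3, ],
              xyzt_units = 10L)
  img <- RNifti::asNifti(arr, reference = hdr)
  RNifti::writeNifti(img, path, datatype = datatype)
}
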