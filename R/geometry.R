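#' Volume geometry: grid dimensions plus a voxel-to-world affine
#'
#' A `volume_geometry` ties a 3-D voxel grid to world (MNI) millimetre
#' coordinates through a 4x4 affine. The affine follows the NIfTI convention
#' (it maps *0-based* voxel indices to mm); the R-facing API uses 1-based
#' voxel indices throughout and the converters account for the offset.
#'
#' @param dims integer vector of length 3, grid size along x/y/z.
#' @param affine 4x4 numeric matrix mapping homogeneous 0-based voxel indices
#'   to world mm. If `NULL`, a diagonal affine with spacing `voxel_size` is
#'   built, centred so that world (0,0,0) falls at the grid centre unless
#'   `origin` (world mm of voxel \[1,1,1\]) is given.
#' @param voxel_size numeric length-3 voxel spacing in mm (used only when
#'   `affine` is `NULL`).
#' @param origin world mm of the first voxel (used only when `affine` is
#'   `NULL`).
#' @return an object of class `volume_geometry` with fields `dims`,
#'   `affine`, `voxel_size`.
#' @export
volume_geometry <- function(dims, affine = NULL, voxel_size = c(2, 2, 2),
                            origin = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L))
    stop("'dims' must be three integers >= 1")
  if (is.null(affine)) {
    voxel_size <- rep_len(as.numeric(voxel_size), 3L)
    if (any(voxel_size <= 0)) stop("'voxel_size' components must be > 0")
    if (is.null(origin)) origin <- -(dims - 1) / 2 * voxel_size
    affine <- diag(c(voxel_size, 1))
    affine[1:3, 4] <- origin
  }
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) || !all(is.finite(affine)))
    stop("'affine' must be a finite 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps * 64)
    stop("'affine' must be invertible")
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(vs <= 0)) stop("voxel sizes implied by 'affine' must be > 0")
  structure(list(dims = dims, affine = unname(affine), voxel_size = vs),
            class = "volume_geometry")
}

#' @export
print.volume_geometry <- function(x, ...) {
  cat("<volume_geometry> ", paste(x$dims, collapse = " x "),
      " voxels, spacing ", paste(signif(x$voxel_size, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

geom_equal <- function(a, b, tol = 1e-6) {
  identical(a$dims, b$dims) && max(abs(a$affine - b$affine)) < tol
}

stopifnot_same_geometry <- function(a, b) {
  if (!geom_equal(a$geometry, b$geometry))
    stop("geometries do not match between '", deparse(substitute(a)),
         "' and '", deparse(substitute(b)), "'")
  invisible(NULL)
}

#' Convert voxel indices to world (MNI) millimetres and back
#'
#' `voxel_to_world()` applies the affine exactly; `world_to_voxel()` applies
#' the inverse affine and rounds to the nearest voxel, erroring for points
#' that land outside the volume.
#'
#' @param idx integer vector of length 3 (1-based voxel index) or an n x 3
#'   matrix of indices.
#' @param geom a [volume_geometry()].
#' @return `voxel_to_world()`: numeric mm triple (or n x 3 matrix);
#'   `world_to_voxel()`: integer triple (or n x 3 matrix) of 1-based indices.
#' @export
voxel_to_world <- function(idx, geom) {
  m <- rbind_coords(idx)
  if (any(m < 1L) || any(sweep(m, 2, geom$dims, ">")))
    stop("voxel index out of volume")
  w <- cbind(m - 1, 1) %*% t(geom$affine)
  out <- w[, 1:3, drop = FALSE]
  if (is.null(dim(idx)) && length(idx) == 3L) drop(out) else out
}

#' @rdname voxel_to_world
#' @param world numeric mm triple or n x 3 matrix of world coordinates.
#' @export
world_to_voxel <- function(world, geom) {
  m <- rbind_coords(world)
  v <- cbind(m, 1) %*% t(solve(geom$affine))
  idx <- round(v[, 1:3, drop = FALSE]) + 1
  if (any(idx < 1L) || any(sweep(idx, 2, geom$dims, ">")))
    stop("world point maps outside the volume")
  storage.mode(idx) <- "integer"
  if (is.null(dim(world)) && length(world) == 3L) drop(idx) else idx
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) {
    if (length(x) != 3L) stop("coordinate must have length 3")
    matrix(as.numeric(x), 1L, 3L)
  } else {
    if (ncol(x) != 3L) stop("coordinate matrix must have 3 columns")
    m <- as.matrix(x)
    storage.mode(m) <- "double"
    m
  }
}

# world-mm coordinates of every voxel centre, as an (nx*ny*nz) x 3 matrix in
# R array (column-major) order
all_voxel_world_coords <- function(geom) {
  d <- geom$dims
  idx <- cbind(rep.int(seq_len(d[1]), d[2] * d[3]),
               rep.int(rep(seq_len(d[2]), each = d[1]), d[3]),
               rep(seq_len(d[3]), each = d[1] * d[2]))
  cbind(idx - 1, 1) %*% t(geom$affine) |> (\(w) w[, 1:3, drop = FALSE])()
}
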