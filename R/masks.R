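#' Spherical region-of-interest mask
#'
#' Builds the mask of voxels whose centre (in world mm) lies within
#' `radius` mm (inclusive) of `center`. This is the primitive behind the
#' 10-mm sgACC seed sphere, the four 20-mm DLPFC search spheres, and the
#' 8-mm target ROIs of the symptom-association analysis.
#'
#' @param center world-mm triple.
#' @param radius sphere radius in mm, > 0.
#' @param geom a [volume_geometry()].
#' @param name mask label.
#' @return a [binary_mask()]; errors if no voxel centre falls inside the
#'   sphere.
#' @export
make_sphere_mask <- function(center, radius, geom, name = "sphere") {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("'radius' must be a positive scalar (mm)")
  center <- as.numeric(center)
  if (length(center) != 3L || !all(is.finite(center)))
    stop("'center' must be a finite mm triple")
  w <- all_voxel_world_coords(geom)
  d2 <- (w[, 1] - center[1])^2 + (w[, 2] - center[2])^2 + (w[, 3] - center[3])^2
  inside <- d2 <= radius^2
  if (!any(inside))
    stop("sphere at (", paste(center, collapse = ", "), "), radius ", radius,
         " mm lies entirely outside the volume")
  binary_mask(array(inside, dim = geom$dims), geom, name = name)
}

#' Four-sphere DLPFC search mask for the seed-based algorithm
#'
#' The DLPFC search space is the union of four 20-mm-radius spheres centred
#' at the left BA9, BA46, "5-cm" and F3-beam literature coordinates,
#' intersected with a gray-matter mask supplied by the user.
#'
#' @param gray_matter a [binary_mask()] gray-matter mask.
#' @param centers 4 x 3 matrix of sphere centres in MNI mm; the default is
#'   the standard set.
#' @param radius sphere radius in mm (default 20).
#' @return a [binary_mask()]; errors if the intersection with gray matter is
#'   empty.
#' @export
build_rsa_dlpfc_mask <- function(gray_matter,
                                 centers = rsa_dlpfc_sphere_centers(),
                                 radius = 20) {
  geom <- gray_matter$geometry
  w <- all_voxel_world_coords(geom)
  inside <- rep(FALSE, nrow(w))
  for (i in seq_len(nrow(centers))) {
    d2 <- (w[, 1] - centers[i, 1])^2 + (w[, 2] - centers[i, 2])^2 +
      (w[, 3] - centers[i, 3])^2
    inside <- inside | d2 <= radius^2
  }
  data <- array(inside, dim = geom$dims) & gray_matter$data
  if (!any(data))
    stop("DLPFC sphere union does not intersect the gray-matter mask")
  binary_mask(data, geom, name = "dlpfc_rsa")
}

#' @rdname build_rsa_dlpfc_mask
#' @export
rsa_dlpfc_sphere_centers <- function() {
  rbind(ba9 = c(-36, 39, 43),
        ba46 = c(-44, 40, 29),
        five_cm = c(-41, 16, 54),
        f3_beam = c(-37, 26, 49))
}

#' Default sgACC seed sphere (10 mm radius at MNI \[6, 16, -10\])
#'
#' @param geom a [volume_geometry()].
#' @return a [binary_mask()].
#' @export
make_sgacc_mask <- function(geom) {
  make_sphere_mask(c(6, 16, -10), 10, geom, name = "sgacc")
}

#' Mask from an integer atlas label volume
#'
#' Selects the voxels of an atlas (e.g. Brodmann areas: left BA46 for the
#' clustering algorithm's DLPFC, bilateral BA25 for sgACC) whose label is in
#' `labels`.
#'
#' @param atlas a [weight_map()]-like object holding integer labels, or a
#'   3-D integer array.
#' @param labels integer vector of labels to select.
#' @param geom geometry, required when `atlas` is a bare array.
#' @param name mask label.
#' @return a [binary_mask()]; errors if any requested label is absent.
#' @export
load_label_mask <- function(atlas, labels, geom = NULL, name = "label_mask") {
  if (inherits(atlas, "weight_map") || inherits(atlas, "binary_mask")) {
    geom <- atlas$geometry
    vol <- atlas$data
  } else {
    if (is.null(geom)) stop("'geom' is required when 'atlas' is an array")
    vol <- atlas
  }
  if (max(abs(vol - round(vol)), na.rm = TRUE) > 0)
    stop("'atlas' must be an integer label volume")
  labels <- as.integer(labels)
  present <- labels %in% unique(as.vector(vol))
  if (!all(present))
    stop("label(s) absent from atlas: ", paste(labels[!present], collapse = ", "))
  binary_mask(array(vol %in% labels, dim = geom$dims), geom, name = name)
}
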