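#' Connected components of a binary mask
#'
#' Labels the spatially contiguous components of a mask under 6- (faces),
#' 18- (faces+edges) or 26- (faces+edges+corners) connectivity. Component
#' ids are assigned in order of each component's smallest linearized voxel
#' index, making the labeling invariant to voxel enumeration order.
#'
#' @param mask a [binary_mask()].
#' @param connectivity 6, 18 or 26 (default 26).
#' @return integer 3-D array, 0 outside the mask, component id inside.
#' @export
connected_components <- function(mask, connectivity = 26) {
  offsets <- connectivity_offsets(connectivity)
  d <- mask$geometry$dims
  vox <- mask_voxel_matrix(mask)
  n <- nrow(vox)
  labels <- array(0L, dim = d)
  if (n == 0L) return(labels)
  # row id of each in-mask voxel, addressable by (x,y,z)
  rowid <- array(0L, dim = d)
  rowid[vox] <- seq_len(n)
  comp <- integer(n)
  next_id <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    next_id <- next_id + 1L
    comp[start] <- next_id
    frontier <- start
    while (length(frontier)) {
      fc <- vox[frontier, , drop = FALSE]
      nb_ids <- integer(0)
      for (k in seq_len(nrow(offsets))) {
        nc <- fc
        nc[, 1] <- nc[, 1] + offsets[k, 1]
        nc[, 2] <- nc[, 2] + offsets[k, 2]
        nc[, 3] <- nc[, 3] + offsets[k, 3]
        ok <- nc[, 1] >= 1L & nc[, 1] <= d[1] &
          nc[, 2] >= 1L & nc[, 2] <= d[2] &
          nc[, 3] >= 1L & nc[, 3] <= d[3]
        if (!any(ok)) next
        ids <- rowid[nc[ok, , drop = FALSE]]
        nb_ids <- c(nb_ids, ids[ids > 0L])
      }
      nb_ids <- unique(nb_ids)
      nb_ids <- nb_ids[comp[nb_ids] == 0L]
      comp[nb_ids] <- next_id
      frontier <- nb_ids
    }
  }
  labels[vox] <- comp
  labels
}

connectivity_offsets <- function(connectivity) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("'connectivity' must be 6, 18 or 26")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  l1 <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = l1 == 1,
                 "18" = l1 >= 1 & l1 <= 2,
                 "26" = l1 >= 1)
  g[keep, , drop = FALSE]
}

#' Largest contiguous cluster of a mask
#'
#' Returns the connected component with the most voxels; ties are broken in
#' favour of the component containing the lowest linearized voxel index.
#'
#' @inheritParams connected_components
#' @return a [binary_mask()] covering only the winning component.
#' @export
largest_connected_cluster <- function(mask, connectivity = 26) {
  if (!any(mask$data)) stop("mask '", mask$name, "' is empty")
  labels <- connected_components(mask, connectivity)
  sizes <- tabulate(labels[labels > 0L])
  # ids are ordered by smallest member linear index, so which.max resolves
  # size ties toward the lowest-index component
  win <- which.max(sizes)
  binary_mask(array(labels == win, dim = dim(labels)), mask$geometry,
              name = paste0(mask$name, "_largest_cluster"))
}

#' Centroid of a cluster in world mm
#'
#' Unweighted mean of the member-voxel centre coordinates.
#'
#' @param cluster a non-empty [binary_mask()].
#' @return numeric mm triple.
#' @export
cluster_centroid <- function(cluster) {
  if (!any(cluster$data)) stop("cannot take the centroid of an empty mask")
  colMeans(mask_world_coords(cluster))
}
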