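# shared fixtures and independent oracles, all built in code

tiny_geom <- function(dims = c(8, 8, 8), voxel_size = 2, origin = NULL) {
  volume_geometry(dims, voxel_size = rep(voxel_size, 3), origin = origin)
}

# bold_run from an nvox x nt matrix laid onto the first voxels of a grid
run_from_matrix <- function(ts, dims = NULL, tr = 1) {
  nv <- nrow(ts); nt <- ncol(ts)
  if (is.null(dims)) dims <- c(nv, 1, 1)
  arr <- array(0, dim = c(dims, nt))
  flat <- matrix(arr, ncol = nt)
  flat[seq_len(nv), ] <- ts
  bold_run(array(flat, dim = c(dims, nt)), tiny_geom(dims), tr = tr)
}

mask_first_voxels <- function(n, dims, geom = tiny_geom(dims)) {
  m <- array(FALSE, dim = dims)
  m[seq_len(n)] <- TRUE
  binary_mask(m, geom)
}

random_mask <- function(dims, p = 0.3, geom = tiny_geom(dims)) {
  binary_mask(array(stats::runif(prod(dims)) < p, dim = dims), geom,
              require_nonempty = FALSE)
}

# --- oracle: exhaustive sphere membership scan ------------------------------
sphere_oracle_count <- function(center, radius, geom) {
  n <- 0L
  for (i in seq_len(geom$dims[1]))
    for (j in seq_len(geom$dims[2]))
      for (k in seq_len(geom$dims[3])) {
        w <- voxel_to_world(c(i, j, k), geom)
        if (sqrt(sum((w - center)^2)) <= radius) n <- n + 1L
      }
  n
}

# --- oracle: stack-based flood fill, loops only -----------------------------
flood_fill_components <- function(mask, connectivity) {
  d <- dim(mask$data)
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  l1 <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  linf <- pmax(abs(g$dx), abs(g$dy), abs(g$dz))
  offs <- g[switch(as.character(connectivity),
                   "6" = l1 == 1, "18" = l1 >= 1 & l1 <= 2,
                   "26" = linf == 1 & l1 >= 1), ]
  labels <- array(0L, dim = d)
  cur <- 0L
  for (lin in which(as.vector(mask$data))) {
    if (labels[lin] != 0L) next
    cur <- cur + 1L
    stack <- list(arrayInd(lin, d)[1, ])
    labels[lin] <- cur
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (r in seq_len(nrow(offs))) {
        nb <- v + c(offs$dx[r], offs$dy[r], offs$dz[r])
        if (any(nb < 1) || any(nb > d)) next
        if (mask$data[nb[1], nb[2], nb[3]] &&
            labels[nb[1], nb[2], nb[3]] == 0L) {
          labels[nb[1], nb[2], nb[3]] <- cur
          stack[[length(stack) + 1L]] <- nb
        }
      }
    }
  }
  labels
}

same_partition <- function(a, b) {
  # exact agreement up to relabeling
  length(a) == length(b) &&
    identical(as.vector(unclass(factor(a, levels = unique(a)))),
              as.vector(unclass(factor(b, levels = unique(b)))))
}

# --- oracle: naive greedy adjacency-constrained average-linkage merge -------
greedy_merge_oracle <- function(dist, adjacency, stop = 0.5) {
  n <- nrow(dist)
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1L) break
    best <- NULL; best_d <- Inf; best_key <- c(Inf, Inf)
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      ca <- clusters[[a]]; cb <- clusters[[b]]
      adj <- FALSE
      for (va in ca) for (vb in cb) if (adjacency[va, vb]) adj <- TRUE
      if (!adj) next
      dd <- mean(dist[ca, cb])
      key <- c(min(min(ca), min(cb)), max(min(ca), min(cb)))
      if (dd < best_d - 1e-15 ||
          (abs(dd - best_d) <= 1e-15 &&
           (key[1] < best_key[1] ||
            (key[1] == best_key[1] && key[2] < best_key[2])))) {
        best <- c(a, b); best_d <- dd; best_key <- key
      }
    }
    if (is.null(best) || best_d > stop) break
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1L]] <- merged
  }
  labels <- integer(n)
  ord <- order(vapply(clusters, min, 1L))
  for (k in seq_along(ord)) labels[clusters[[ord[k]]]] <- k
  labels
}

# small planted cohort shared by several tests (cheap: 1 subject)
planted_subject <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- cohort_spec(n_subjects = 1, seed = 20260925)
      cache <<- list(spec = spec, sub = simulate_subject(spec, 1))
    }
    cache
  }
})
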