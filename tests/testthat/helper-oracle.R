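# Independent brute-force oracles: voxel-center coordinates and pairwise
# minimum distances are recomputed here from first principles (no calls into
# the package's transform code), matching the documented convention:
# positive outside = distance to nearest target voxel center, negative inside
# = -distance to nearest non-target center, with the grid padded by one
# background layer.

oracle_centers <- function(g) {
  as.matrix(expand.grid(
    g$origin[1] + (seq_len(g$shape[1]) - 0.5) * g$spacing[1],
    g$origin[2] + (seq_len(g$shape[2]) - 0.5) * g$spacing[2],
    g$origin[3] + (seq_len(g$shape[3]) - 0.5) * g$spacing[3]))
}

# minimum Euclidean distance from each row of `points` to any row of `refs`
oracle_min_dist <- function(points, refs) {
  stopifnot(nrow(refs) > 0)
  out <- numeric(nrow(points))
  step <- max(1L, floor(2e6 / nrow(refs)))
  r2 <- rowSums(refs^2)
  for (s in seq(1, nrow(points), by = step)) {
    e <- min(s + step - 1, nrow(points))
    P <- points[s:e, , drop = FALSE]
    d2 <- outer(rowSums(P^2), r2, "+") - 2 * P %*% t(refs)
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

# coordinates of all non-target voxel centers, including the one-voxel padded
# background shell around the grid
oracle_background_centers <- function(mask) {
  g <- mask$geometry
  idx <- as.matrix(expand.grid(0:(g$shape[1] + 1L), 0:(g$shape[2] + 1L),
                               0:(g$shape[3] + 1L))) - 1L
  inside <- idx[, 1] >= 0 & idx[, 1] < g$shape[1] &
            idx[, 2] >= 0 & idx[, 2] < g$shape[2] &
            idx[, 3] >= 0 & idx[, 3] < g$shape[3]
  v <- as.vector(mask$voxels)
  lin <- 1L + idx[, 1] + g$shape[1] * (idx[, 2] + g$shape[2] * idx[, 3])
  keep <- !inside | !v[ifelse(inside, lin, 1L)]
  sweep(sweep(idx[keep, , drop = FALSE] + 0.5, 2, g$spacing, "*"),
        2, g$origin, "+")
}

# signed distance at a subset of voxels (logical array or NULL for all)
oracle_signed_distance <- function(target, at = NULL) {
  g <- target$geometry
  if (is.null(at)) at <- array(TRUE, g$shape)
  cc <- oracle_centers(g)
  v <- as.vector(target$voxels)
  sel <- as.vector(at)
  tc <- cc[v, , drop = FALSE]
  bg <- oracle_background_centers(target)
  out <- numeric(sum(sel))
  inside_sel <- v[sel]
  pts <- cc[sel, , drop = FALSE]
  if (any(!inside_sel))
    out[!inside_sel] <- oracle_min_dist(pts[!inside_sel, , drop = FALSE], tc)
  if (any(inside_sel))
    out[inside_sel] <- -oracle_min_dist(pts[inside_sel, , drop = FALSE], bg)
  out
}

# random blobby structure: union of 1-2 ellipsoids with at least one voxel
random_structure <- function(g, label = "S") {
  cc <- oracle_centers(g)
  extent <- g$shape * g$spacing
  v <- rep(FALSE, nrow(cc))
  for (k in seq_len(sample(1:2, 1))) {
    ctr <- g$origin + runif(3, 0.2, 0.8) * extent
    semi <- runif(3, 0.1, 0.35) * extent
    v <- v | (rowSums(sweep(sweep(cc, 2, ctr, "-"), 2, semi, "/")^2) <= 1)
  }
  if (!any(v)) v[sample(length(v), 1)] <- TRUE
  structure_mask(array(v, g$shape), g, label = label)
}

random_geometry <- function(max_side = 16) {
  grid_geometry(sample(6:max_side, 3, replace = TRUE),
                spacing = runif(3, 0.8, 3),
                origin = runif(3, -10, 10))
}
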