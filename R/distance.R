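#' Signed Euclidean distance field from a target structure
#'
#' Computes, at every voxel center, the minimum Euclidean distance (mm,
#' respecting anisotropic spacing) to the target: positive outside the target
#' (distance to the nearest target voxel center) and negative inside (minus the
#' distance to the nearest non-target voxel center). The grid is treated as
#' surrounded by one layer of background, so a target that fills the whole grid
#' still gets finite, non-positive values. This is the distance \code{d(p, T)}
#' that the overlap volume histogram accumulates.
#'
#' The transform is an exact anisotropic Euclidean distance transform
#' (separable lower-envelope algorithm), so values agree with a brute-force
#' pairwise minimum over voxel centers to floating-point precision.
#'
#' @param target a non-empty \code{\link{structure_mask}}.
#' @return A \code{\link{scalar_field}} of signed distances in mm.
#' @examples
#' g <- grid_geometry(c(9, 9, 9), spacing = c(1, 1, 1))
#' v <- array(FALSE, c(9, 9, 9)); v[5, 5, 5] <- TRUE
#' sdf <- signed_distance_field(structure_mask(v, g, "PTV"))
#' sdf$values[8, 5, 5]  # 3 mm: three voxel steps from the target center
#' @export
signed_distance_field <- function(target) {
  stopifnot(inherits(target, "structure_mask"))
  if (!any(target$voxels))
    stop("target structure is empty; a signed distance field needs at least one target voxel",
         call. = FALSE)
  g <- target$geometry
  d_out2 <- edt_squared_cpp(as.logical(target$voxels), g$shape, g$spacing)
  # inside distance: EDT of the complement on a one-voxel padded grid, so the
  # grid boundary counts as background
  pshape <- g$shape + 2L
  padded <- array(TRUE, dim = pshape)
  padded[2:(pshape[1] - 1L), 2:(pshape[2] - 1L), 2:(pshape[3] - 1L)] <-
    !target$voxels
  d_in2 <- array(edt_squared_cpp(as.logical(padded), pshape, g$spacing),
                 dim = pshape)
  d_in2 <- d_in2[2:(pshape[1] - 1L), 2:(pshape[2] - 1L), 2:(pshape[3] - 1L)]
  sd <- sqrt(array(d_out2, dim = g$shape)) - sqrt(d_in2)
  scalar_field(sd, g, unit = "mm")
}
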