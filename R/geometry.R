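#' Voxel-grid geometry
#'
#' Describes the physical embedding of a 3-D voxel grid: the number of voxels
#' along each axis, the voxel spacing in mm, and the physical position of the
#' grid corner. Voxel centers sit at \code{origin + (index - 1 + 0.5) * spacing}
#' for 1-based indices, so all distances computed on the grid are in mm.
#'
#' @param shape integer vector of length 3, voxel counts per axis (each >= 1).
#' @param spacing numeric vector of length 3, mm per voxel per axis (each > 0).
#' @param origin numeric vector of length 3, physical coordinates (mm) of the
#'   grid corner. Defaults to the grid centered on the physical origin.
#' @return An object of class \code{grid_geometry}.
#' @examples
#' g <- grid_geometry(c(10, 10, 5), spacing = c(1, 1, 3))
#' voxel_volume(g)  # 3 mm^3
#' @export
grid_geometry <- function(shape, spacing = c(1, 1, 1), origin = NULL) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be three positive voxel counts", call. = FALSE)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive lengths (mm)", call. = FALSE)
  if (is.null(origin)) origin <- -shape * spacing / 2
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite coordinates (mm)", call. = FALSE)
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @rdname grid_geometry
#' @param geometry a \code{grid_geometry}.
#' @export
voxel_volume <- function(geometry) prod(geometry$spacing)

#' @rdname grid_geometry
#' @export
voxel_diagonal <- function(geometry) sqrt(sum(geometry$spacing^2))

same_geometry <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_geometry_mismatch <- function(what) {
  stop(sprintf("geometry mismatch: %s; resample explicitly first (see resample_mask / resample_dose)",
               what), call. = FALSE)
}

# Physical center coordinates (mm) of all voxels, as an n x 3 matrix in array
# order; heavy for big grids, used by phantoms/tests, not by the EDT.
voxel_centers <- function(geometry) {
  s <- geometry$shape; sp <- geometry$spacing; o <- geometry$origin
  cx <- o[1] + (seq_len(s[1]) - 0.5) * sp[1]
  cy <- o[2] + (seq_len(s[2]) - 0.5) * sp[2]
  cz <- o[3] + (seq_len(s[3]) - 0.5) * sp[3]
  cbind(rep(cx, times = s[2] * s[3]),
        rep(rep(cy, each = s[1]), times = s[3]),
        rep(cz, each = s[1] * s[2]))
}

# Per-axis center coordinate vectors (list of 3), cheaper than voxel_centers.
axis_centers <- function(geometry) {
  lapply(1:3, function(i)
    geometry$origin[i] + (seq_len(geometry$shape[i]) - 0.5) * geometry$spacing[i])
}

#' Binary structure mask on a voxel grid
#'
#' @param voxels logical (or coercible) 3-D array of occupancy.
#' @param geometry the \code{\link{grid_geometry}} the mask lives on.
#' @param label structure name, e.g. \code{"PTV"}, \code{"Heart"}.
#' @param require_nonempty error if the mask has no true voxel (targets and
#'   organs must have positive volume).
#' @return An object of class \code{structure_mask}.
#' @export
structure_mask <- function(voxels, geometry, label = "structure",
                           require_nonempty = TRUE) {
  stopifnot(inherits(geometry, "grid_geometry"))
  voxels <- array(as.logical(voxels) & !is.na(voxels), dim = geometry$shape)
  if (!identical(dim(voxels), as.integer(geometry$shape)))
    stop("mask array shape does not match geometry", call. = FALSE)
  if (require_nonempty && !any(voxels))
    stop(sprintf("structure '%s' is empty: a target or organ must contain at least one voxel",
                 label), call. = FALSE)
  structure(list(geometry = geometry, voxels = voxels, label = label),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> '%s': %d voxels, %.1f cm^3\n", x$label,
              sum(x$voxels), structure_volume(x) / 1000))
  invisible(x)
}

#' Physical volume of a mask (mm^3)
#' @param mask a \code{structure_mask}.
#' @export
structure_volume <- function(mask) sum(mask$voxels) * voxel_volume(mask$geometry)

#' Scalar field on a voxel grid
#'
#' Holds per-voxel real values: mm for signed distance fields, Gy for dose.
#'
#' @param values numeric 3-D array, all finite.
#' @param geometry the \code{\link{grid_geometry}}.
#' @param unit free-text unit tag ("mm" or "Gy").
#' @return An object of class \code{scalar_field}.
#' @export
scalar_field <- function(values, geometry, unit = "") {
  stopifnot(inherits(geometry, "grid_geometry"))
  values <- array(as.numeric(values), dim = geometry$shape)
  if (any(!is.finite(values)))
    stop("scalar field values must all be finite", call. = FALSE)
  structure(list(geometry = geometry, values = values, unit = unit),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("<scalar_field> [%s] range %.3f .. %.3f over %d voxels\n",
              x$unit, min(x$values), max(x$values), length(x$values)))
  invisible(x)
}

#' Resample a mask onto another grid (nearest neighbor)
#'
#' Occupancy is categorical, so masks are moved between grids by
#' nearest-neighbor lookup of the source voxel containing each target voxel
#' center; target centers outside the source extent become background. Masks
#' are never resampled implicitly: every cross-grid operation in the package
#' demands matching geometry and points here.
#'
#' @param mask a \code{structure_mask}.
#' @param target_geometry the destination \code{grid_geometry}.
#' @return A \code{structure_mask} on \code{target_geometry}.
#' @export
resample_mask <- function(mask, target_geometry) {
  stopifnot(inherits(mask, "structure_mask"),
            inherits(target_geometry, "grid_geometry"))
  src <- mask$geometry
  ax <- axis_centers(target_geometry)
  idx <- lapply(1:3, function(i) {
    j <- floor((ax[[i]] - src$origin[i]) / src$spacing[i]) + 1L
    j[j < 1L | j > src$shape[i]] <- NA_integer_
    as.integer(j)
  })
  out <- array(FALSE, dim = target_geometry$shape)
  ok1 <- !is.na(idx[[1]]); ok2 <- !is.na(idx[[2]]); ok3 <- !is.na(idx[[3]])
  if (any(ok1) && any(ok2) && any(ok3)) {
    out[ok1, ok2, ok3] <- mask$voxels[idx[[1]][ok1], idx[[2]][ok2], idx[[3]][ok3],
                                      drop = FALSE]
  }
  structure_mask(out, target_geometry, label = mask$label,
                 require_nonempty = FALSE)
}
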