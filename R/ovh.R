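#' Overlap volume histogram (OVH) curve
#'
#' The OVH of an organ at risk O with respect to a target T maps a signed
#' expansion distance d (mm) to the fraction of O's volume lying within
#' distance d of T: \code{OVH(d) = |{p in O : d(p, T) <= d}| / |O|}. It is a
#' pure-geometry descriptor of how closely an organ wraps the target.
#'
#' @param distances strictly increasing distance levels (mm; negative values
#'   refer to organ voxels inside the target).
#' @param fractions cumulative volume fractions in [0, 1], non-decreasing,
#'   ending at 1.
#' @param oar_label,ptv_label structure names.
#' @param bin_width distance bin width (mm).
#' @return An object of class \code{ovh_curve}.
#' @export
ovh_curve <- function(distances, fractions, oar_label = "OAR",
                      ptv_label = "PTV", bin_width = NA_real_) {
  distances <- as.numeric(distances); fractions <- as.numeric(fractions)
  if (length(distances) != length(fractions) || length(distances) < 1L)
    stop("`distances` and `fractions` must be equal-length, non-empty",
         call. = FALSE)
  if (any(diff(distances) <= 0))
    stop("OVH distances must be strictly increasing", call. = FALSE)
  if (any(diff(fractions) < -1e-12))
    stop("OVH fractions must be non-decreasing", call. = FALSE)
  if (any(fractions < -1e-12 | fractions > 1 + 1e-12))
    stop("OVH fractions must lie in [0, 1]", call. = FALSE)
  if (abs(fractions[length(fractions)] - 1) > 1e-9)
    stop("OVH must end at fraction 1 (full organ coverage)", call. = FALSE)
  structure(list(distances = distances, fractions = pmin(pmax(fractions, 0), 1),
                 oar_label = oar_label, ptv_label = ptv_label,
                 bin_width = bin_width),
            class = "ovh_curve")
}

#' @export
print.ovh_curve <- function(x, ...) {
  cat(sprintf("<ovh_curve> %s vs %s: %d bins over [%.1f, %.1f] mm\n",
              x$oar_label, x$ptv_label, length(x$distances),
              min(x$distances), max(x$distances)))
  invisible(x)
}

#' Compute the OVH of an organ at risk against a target
#'
#' Bins the signed distances from every organ voxel to the target into a
#' cumulative histogram. Distances come from
#' \code{\link{signed_distance_field}}; bin edges are multiples of
#' \code{bin_width}, starting one bin below the closest organ voxel (fraction
#' 0) and ending at the first edge that covers the whole organ (fraction 1).
#'
#' @param oar organ-at-risk \code{\link{structure_mask}} (non-empty).
#' @param target target \code{\link{structure_mask}}; must share the organ's
#'   grid (resample explicitly otherwise).
#' @param bin_width distance bin width in mm (default 1.0, small enough that
#'   interpolated \code{\link{l_x}} error is bounded by the bin).
#' @param sdf optional precomputed signed distance field of \code{target},
#'   to amortize the transform across several organs.
#' @return An \code{\link{ovh_curve}}.
#' @export
compute_ovh <- function(oar, target, bin_width = 1.0, sdf = NULL) {
  stopifnot(inherits(oar, "structure_mask"), inherits(target, "structure_mask"))
  if (!same_geometry(oar$geometry, target$geometry))
    stop_geometry_mismatch(sprintf("OAR '%s' and target '%s' are on different grids",
                                   oar$label, target$label))
  if (!any(oar$voxels)) stop("OAR mask is empty", call. = FALSE)
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("`bin_width` must be a positive length in mm", call. = FALSE)
  if (is.null(sdf)) sdf <- signed_distance_field(target)
  if (!same_geometry(sdf$geometry, oar$geometry))
    stop_geometry_mismatch("precomputed distance field is on a different grid")
  d <- sdf$values[oar$voxels]
  e0 <- bin_width * (ceiling(min(d) / bin_width - 1e-9) - 1)
  e1 <- bin_width * ceiling(max(d) / bin_width - 1e-9)
  edges <- seq(e0, e1, by = bin_width)
  counts <- findInterval(edges + 1e-9, sort(d))
  ovh_curve(edges, counts / length(d), oar_label = oar$label,
            ptv_label = target$label, bin_width = bin_width)
}

#' L_x: PTV expansion distance enclosing x percent of an organ
#'
#' The generalized inverse of the OVH: the smallest distance d with
#' \code{OVH(d) >= x/100}, linearly interpolated between adjacent bins.
#' \code{l_x(curve, 100)} is the curve's final distance (full coverage).
#'
#' @param curve an \code{\link{ovh_curve}}.
#' @param x percent volume in (0, 100]. May be a vector.
#' @return Distance(s) in mm.
#' @export
l_x <- function(curve, x) {
  stopifnot(inherits(curve, "ovh_curve"))
  if (any(!is.finite(x)) || any(x <= 0) || any(x > 100))
    stop("`x` must be a percent volume in (0, 100]", call. = FALSE)
  vapply(x, function(xi) {
    q <- xi / 100
    f <- curve$fractions; d <- curve$distances
    i <- which(f >= q - 1e-12)[1]
    if (is.na(i)) return(d[length(d)])
    if (i == 1L || f[i] - f[i - 1L] < 1e-15) return(d[i])
    d[i - 1L] + (q - f[i - 1L]) / (f[i] - f[i - 1L]) * (d[i] - d[i - 1L])
  }, numeric(1))
}

#' Read/write OVH curves as two-column CSV
#'
#' The CSV carries \code{distance_mm,fraction} columns, preceded by comment
#' lines (\code{#}) recording the structure labels and bin width.
#'
#' @param curve an \code{\link{ovh_curve}}.
#' @param path CSV file path.
#' @return \code{write_ovh_csv} returns the path invisibly; \code{read_ovh_csv}
#'   returns an \code{\link{ovh_curve}}.
#' @export
write_ovh_csv <- function(curve, path) {
  stopifnot(inherits(curve, "ovh_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# oar_label: %s", curve$oar_label),
               sprintf("# ptv_label: %s", curve$ptv_label),
               sprintf("# bin_width_mm: %.10g", curve$bin_width),
               "distance_mm,fraction"), con)
  utils::write.table(data.frame(curve$distances, curve$fractions), con,
                     sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ovh_csv
#' @export
read_ovh_csv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read OVH curve: '%s' does not exist", path),
         call. = FALSE)
  hdr <- readLines(path, n = 10L)
  meta <- function(key, default) {
    ln <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (length(ln) == 0L) default else trimws(sub("^# [a-z_]+:", "", ln[1]))
  }
  tab <- utils::read.csv(path, comment.char = "#")
  ovh_curve(tab$distance_mm, tab$fraction,
            oar_label = meta("oar_label", "OAR"),
            ptv_label = meta("ptv_label", "PTV"),
            bin_width = as.numeric(meta("bin_width_mm", NA)))
}
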