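#' Cumulative dose-volume histogram (DVH) curve
#'
#' Maps a dose level t (Gy) to the fraction of a structure's volume receiving
#' at least t. Starts at fraction 1 for t = 0 and falls to 0 just above the
#' maximum structure dose.
#'
#' @param doses strictly increasing dose levels (Gy), starting at 0.
#' @param fractions non-increasing cumulative fractions, \code{fractions[1] = 1}
#'   and final fraction 0.
#' @param structure_label structure name.
#' @param bin_width dose bin width (Gy).
#' @return An object of class \code{dvh_curve}.
#' @export
dvh_curve <- function(doses, fractions, structure_label = "structure",
                      bin_width = NA_real_) {
  doses <- as.numeric(doses); fractions <- as.numeric(fractions)
  if (length(doses) != length(fractions) || length(doses) < 2L)
    stop("`doses` and `fractions` must be equal-length with at least two bins",
         call. = FALSE)
  if (abs(doses[1]) > 1e-9 || any(diff(doses) <= 0))
    stop("DVH doses must be strictly increasing and start at 0 Gy", call. = FALSE)
  if (any(diff(fractions) > 1e-12))
    stop("DVH fractions must be non-increasing", call. = FALSE)
  if (abs(fractions[1] - 1) > 1e-9 || abs(fractions[length(fractions)]) > 1e-9)
    stop("DVH must start at fraction 1 and end at fraction 0", call. = FALSE)
  structure(list(doses = doses, fractions = pmin(pmax(fractions, 0), 1),
                 structure_label = structure_label, bin_width = bin_width),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> '%s': %d bins up to %.2f Gy\n", x$structure_label,
              length(x$doses), max(x$doses)))
  invisible(x)
}

#' Compute a cumulative DVH over a structure
#'
#' @param dose a \code{\link{scalar_field}} of dose in Gy.
#' @param mask a non-empty \code{\link{structure_mask}} on the same grid.
#' @param bin_width dose bin width in Gy (default 0.05).
#' @return A \code{\link{dvh_curve}}.
#' @export
compute_dvh <- function(dose, mask, bin_width = 0.05) {
  stopifnot(inherits(dose, "scalar_field"), inherits(mask, "structure_mask"))
  if (!same_geometry(dose$geometry, mask$geometry))
    stop_geometry_mismatch(sprintf("dose grid and structure '%s' differ", mask$label))
  if (!any(mask$voxels)) stop("structure mask is empty", call. = FALSE)
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("`bin_width` must be a positive dose in Gy", call. = FALSE)
  d <- dose$values[mask$voxels]
  if (any(d < -1e-9))
    stop("dose field contains negative values", call. = FALSE)
  d <- pmax(d, 0)
  e1 <- bin_width * (floor(max(d) / bin_width + 1e-9) + 1)
  edges <- seq(0, e1, by = bin_width)
  n_lt <- findInterval(edges - 1e-9, sort(d))
  dvh_curve(edges, (length(d) - n_lt) / length(d),
            structure_label = mask$label, bin_width = bin_width)
}

#' D_x: dose received by the hottest x percent of a structure
#'
#' The generalized inverse of the cumulative DVH: the smallest dose t whose
#' cumulative fraction is at most x/100, linearly interpolated between bins
#' (ties resolved toward the lower dose). Non-increasing in x.
#'
#' @param dvh a \code{\link{dvh_curve}}.
#' @param x percent volume in (0, 100]. May be a vector.
#' @return Dose(s) in Gy.
#' @export
d_x <- function(dvh, x) {
  stopifnot(inherits(dvh, "dvh_curve"))
  if (any(!is.finite(x)) || any(x <= 0) || any(x > 100))
    stop("`x` must be a percent volume in (0, 100]", call. = FALSE)
  vapply(x, function(xi) {
    q <- xi / 100
    f <- dvh$fractions; t <- dvh$doses
    i <- which(f <= q + 1e-12)[1]
    if (is.na(i)) return(t[length(t)])
    if (i == 1L) return(t[1])
    # the curve is identically zero above the maximum structure dose, so the
    # linear wedge of the terminal bin is a binning artifact: resolve the tie
    # toward the lower dose (the last bin edge at or below the maximum)
    if (f[i] < 1e-12) return(t[i - 1L])
    t[i - 1L] + (f[i - 1L] - q) / (f[i - 1L] - f[i]) * (t[i] - t[i - 1L])
  }, numeric(1))
}

#' V_d: percent of a structure receiving at least a dose threshold
#'
#' @param dvh a \code{\link{dvh_curve}}.
#' @param threshold dose in Gy, non-negative. May be a vector.
#' @return Percent volume(s) in [0, 100]; the (approximate) inverse of
#'   \code{\link{d_x}}.
#' @export
v_d <- function(dvh, threshold) {
  stopifnot(inherits(dvh, "dvh_curve"))
  if (any(!is.finite(threshold)) || any(threshold < 0))
    stop("`threshold` must be a non-negative dose in Gy", call. = FALSE)
  vapply(threshold, function(t0) {
    t <- dvh$doses; f <- dvh$fractions
    if (t0 >= t[length(t)]) return(0)
    100 * stats::approx(t, f, xout = t0, rule = 2)$y
  }, numeric(1))
}

#' Mean dose over a structure
#'
#' @inheritParams compute_dvh
#' @return Mean dose in Gy (arithmetic mean over structure voxels).
#' @export
mean_dose <- function(dose, mask) {
  stopifnot(inherits(dose, "scalar_field"), inherits(mask, "structure_mask"))
  if (!same_geometry(dose$geometry, mask$geometry))
    stop_geometry_mismatch(sprintf("dose grid and structure '%s' differ", mask$label))
  if (!any(mask$voxels)) stop("structure mask is empty", call. = FALSE)
  mean(dose$values[mask$voxels])
}

#' Resample a dose grid onto another geometry (trilinear)
#'
#' Dose varies smoothly, so it is moved between grids by trilinear
#' interpolation at the target voxel centers; points outside the source grid's
#' voxel-center hull receive 0 Gy. Trilinear interpolation reproduces constant
#' and linear fields exactly.
#'
#' @param dose a \code{\link{scalar_field}}.
#' @param target_geometry the destination \code{\link{grid_geometry}}.
#' @return A \code{\link{scalar_field}} on \code{target_geometry}.
#' @export
resample_dose <- function(dose, target_geometry) {
  stopifnot(inherits(dose, "scalar_field"),
            inherits(target_geometry, "grid_geometry"))
  src <- dose$geometry
  if (same_geometry(src, target_geometry))
    return(scalar_field(dose$values, target_geometry, unit = dose$unit))
  ax <- axis_centers(target_geometry)
  n <- src$shape
  axinfo <- lapply(1:3, function(i) {
    u <- (ax[[i]] - src$origin[i]) / src$spacing[i] - 0.5  # 0-based center index
    valid <- u >= -1e-9 & u <= n[i] - 1 + 1e-9
    u <- pmin(pmax(u, 0), n[i] - 1)
    i0 <- pmin(floor(u), max(n[i] - 2, 0))
    list(i0 = as.integer(i0), w = u - i0, valid = valid)
  })
  ts <- target_geometry$shape
  rep_axis <- function(v, axis) {
    if (axis == 1L) rep(v, times = ts[2] * ts[3])
    else if (axis == 2L) rep(rep(v, each = ts[1]), times = ts[3])
    else rep(v, each = ts[1] * ts[2])
  }
  I0 <- lapply(1:3, function(i) rep_axis(axinfo[[i]]$i0, i))
  W  <- lapply(1:3, function(i) rep_axis(axinfo[[i]]$w, i))
  V  <- rep_axis(axinfo[[1]]$valid, 1) & rep_axis(axinfo[[2]]$valid, 2) &
        rep_axis(axinfo[[3]]$valid, 3)
  vals <- numeric(prod(ts))
  src_v <- dose$values
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- pmin(I0[[1]] + dx, n[1] - 1L)
    iy <- pmin(I0[[2]] + dy, n[2] - 1L)
    iz <- pmin(I0[[3]] + dz, n[3] - 1L)
    w <- (if (dx) W[[1]] else 1 - W[[1]]) *
         (if (dy) W[[2]] else 1 - W[[2]]) *
         (if (dz) W[[3]] else 1 - W[[3]])
    lin <- 1L + ix + n[1] * (iy + n[2] * iz)
    vals <- vals + w * src_v[lin]
  }
  vals[!V] <- 0
  scalar_field(array(vals, dim = ts), target_geometry, unit = dose$unit)
}

#' Conformity index of a plan
#'
#' \code{CI = TV_P^2 / (V_PTV * V_P)}, where TV_P is the target volume covered
#' by the prescription isodose, V_PTV the target volume, and V_P the total
#' volume enclosed by the prescription isodose. CI is in (0, 1]; 1 means the
#' prescription isodose coincides with the target at voxel resolution.
#'
#' @param dose a \code{\link{scalar_field}} of dose in Gy.
#' @param ptv the target \code{\link{structure_mask}} on the same grid.
#' @param prescription prescription dose D_P in Gy (> 0).
#' @return CI, dimensionless.
#' @export
conformity_index <- function(dose, ptv, prescription) {
  stopifnot(inherits(dose, "scalar_field"), inherits(ptv, "structure_mask"))
  if (!same_geometry(dose$geometry, ptv$geometry))
    stop_geometry_mismatch("dose grid and PTV differ")
  if (!is.numeric(prescription) || prescription <= 0)
    stop("`prescription` must be a positive dose in Gy", call. = FALSE)
  vox <- voxel_volume(dose$geometry)
  iso <- dose$values >= prescription - 1e-9
  v_p <- sum(iso) * vox
  if (v_p == 0)
    stop(sprintf("prescription isodose region is empty: maximum dose %.2f Gy is below the %.2f Gy prescription",
                 max(dose$values), prescription), call. = FALSE)
  tv_p <- sum(iso & ptv$voxels) * vox
  v_ptv <- sum(ptv$voxels) * vox
  tv_p^2 / (v_ptv * v_p)
}

#' Homogeneity index of a target DVH
#'
#' \code{HI = (D_2 - D_98) / D_P}; 0 for a perfectly uniform target dose,
#' larger values mean hotter/colder spots relative to prescription.
#'
#' @param dvh the target's \code{\link{dvh_curve}}.
#' @param prescription prescription dose D_P in Gy (> 0).
#' @return HI, dimensionless and non-negative.
#' @export
homogeneity_index <- function(dvh, prescription) {
  stopifnot(inherits(dvh, "dvh_curve"))
  if (!is.numeric(prescription) || prescription <= 0)
    stop("`prescription` must be a positive dose in Gy", call. = FALSE)
  (d_x(dvh, 2) - d_x(dvh, 98)) / prescription
}

#' Evaluate target plan quality (D2/D95/D98, CI, HI)
#'
#' @inheritParams conformity_index
#' @param bin_width DVH dose bin width in Gy.
#' @return An object of class \code{plan_quality}: list with \code{d2},
#'   \code{d95}, \code{d98} (Gy), \code{ci}, \code{hi} and
#'   \code{prescription}.
#' @export
evaluate_plan <- function(dose, ptv, prescription, bin_width = 0.05) {
  dvh <- compute_dvh(dose, ptv, bin_width = bin_width)
  q <- d_x(dvh, c(2, 95, 98))
  structure(list(d2 = q[1], d95 = q[2], d98 = q[3],
                 ci = conformity_index(dose, ptv, prescription),
                 hi = (q[1] - q[3]) / prescription,
                 prescription = prescription),
            class = "plan_quality")
}

#' @export
print.plan_quality <- function(x, ...) {
  cat(sprintf("<plan_quality> D2 %.2f | D95 %.2f | D98 %.2f Gy; CI %.3f; HI %.3f (D_P %.1f Gy)\n",
              x$d2, x$d95, x$d98, x$ci, x$hi, x$prescription))
  invisible(x)
}

#' Read/write a plan-quality record as JSON
#' @param pq a \code{plan_quality} object.
#' @param path JSON file path.
#' @export
write_plan_quality_json <- function(pq, path) {
  stopifnot(inherits(pq, "plan_quality"))
  jsonlite::write_json(unclass(pq), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plan_quality_json
#' @export
read_plan_quality_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x[c("d2", "d95", "d98", "ci", "hi", "prescription")],
            class = "plan_quality")
}

#' Read/write DVH curves as two-column CSV
#'
#' Columns \code{dose_Gy,fraction}, preceded by \code{#} comment lines with the
#' structure label and bin width.
#'
#' @param dvh a \code{\link{dvh_curve}}.
#' @param path CSV file path.
#' @export
write_dvh_csv <- function(dvh, path) {
  stopifnot(inherits(dvh, "dvh_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# structure_label: %s", dvh$structure_label),
               sprintf("# bin_width_gy: %.10g", dvh$bin_width),
               "dose_Gy,fraction"), con)
  utils::write.table(data.frame(dvh$doses, dvh$fractions), con,
                     sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_dvh_csv
#' @export
read_dvh_csv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read DVH curve: '%s' does not exist", path), call. = FALSE)
  hdr <- readLines(path, n = 10L)
  meta <- function(key, default) {
    ln <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (length(ln) == 0L) default else trimws(sub("^# [a-z_]+:", "", ln[1]))
  }
  tab <- utils::read.csv(path, comment.char = "#")
  dvh_curve(tab$dose_Gy, tab$fraction,
            structure_label = meta("structure_label", "structure"),
            bin_width = as.numeric(meta("bin_width_gy", NA)))
}
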