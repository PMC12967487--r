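# Synthetic thorax phantoms: analytic slab/ellipsoid primitives so that every
# geometric ground truth (gaps, laterality, the L->D law under a prescribed
# falloff) is known exactly, which real anatomy never offers.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# logical array of voxels inside an axis-aligned ellipsoid (mm coordinates)
ellipsoid_voxels <- function(geometry, center, semiaxes) {
  ax <- axis_centers(geometry)
  q <- lapply(1:3, function(i) ((ax[[i]] - center[i]) / semiaxes[i])^2)
  s <- geometry$shape
  arr <- rep(q[[1]], times = s[2] * s[3]) +
    rep(rep(q[[2]], each = s[1]), times = s[3]) +
    rep(q[[3]], each = s[1] * s[2])
  array(arr <= 1, dim = s)
}

#' Specification of a synthetic thorax phantom
#'
#' Describes a chest-wall-like planning target hugging the ipsilateral lung,
#' an ellipsoidal heart left of midline, and two ellipsoidal lungs, on a given
#' voxel grid. All lengths in mm. Defaults emulate an adult thorax on a
#' 240 x 240 x 160 mm grid at 2.5 mm isotropic resolution: large enough for
#' stable OVH curves, small enough that a phantom builds in well under a
#' second.
#'
#' @param laterality \code{"left"} or \code{"right"} (treated side).
#' @param plan_type \code{"pmrmrt"} (post-mastectomy, chest wall plus
#'   supraclavicular block) or \code{"bcrt"} (breast-conserving, chest wall
#'   only).
#' @param grid a \code{\link{grid_geometry}}.
#' @param chestwall_thickness_mm radial thickness of the target slab.
#' @param heart_radius_mm heart sphere radius.
#' @param lung_semiaxes_mm length-3 ellipsoid semiaxes for each lung.
#' @param ptv_heart_gap_mm,ptv_lung_gap_mm closest allowed approach of the
#'   target to heart and ipsilateral lung.
#' @param include_supraclavicular add a supraclavicular target block; defaults
#'   to TRUE for \code{pmrmrt}.
#' @param seed integer driving the small anatomical jitter (positions and
#'   sizes), so cohorts of distinct but reproducible patients can be drawn.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(laterality = c("left", "right"),
                         plan_type = c("pmrmrt", "bcrt"),
                         grid = grid_geometry(c(96, 96, 64), c(2.5, 2.5, 2.5)),
                         chestwall_thickness_mm = 15,
                         heart_radius_mm = 30,
                         lung_semiaxes_mm = c(38, 52, 62),
                         ptv_heart_gap_mm = 10,
                         ptv_lung_gap_mm = 3,
                         include_supraclavicular = NULL,
                         seed = 1L) {
  laterality <- match.arg(laterality)
  plan_type <- match.arg(plan_type)
  stopifnot(inherits(grid, "grid_geometry"))
  if (is.null(include_supraclavicular))
    include_supraclavicular <- plan_type == "pmrmrt"
  lens <- c(chestwall_thickness_mm, heart_radius_mm, lung_semiaxes_mm,
            ptv_lung_gap_mm)
  if (any(!is.finite(lens)) || any(lens <= 0) || !is.finite(ptv_heart_gap_mm))
    stop("phantom lengths must be positive and finite", call. = FALSE)
  structure(list(laterality = laterality, plan_type = plan_type, grid = grid,
                 chestwall_thickness_mm = chestwall_thickness_mm,
                 heart_radius_mm = heart_radius_mm,
                 lung_semiaxes_mm = as.numeric(lung_semiaxes_mm),
                 ptv_heart_gap_mm = ptv_heart_gap_mm,
                 ptv_lung_gap_mm = ptv_lung_gap_mm,
                 include_supraclavicular = include_supraclavicular,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Parametric dose model for synthetic plans
#'
#' Dose equals the prescription inside the target and a monotone function of
#' the signed distance to the target outside, plus optional Gaussian noise,
#' truncated at 0 Gy. With zero noise the field is an exact function of
#' distance, which induces an exactly linear (or exactly exponential) L_x to
#' D_x law across phantoms — the analytic ground truth behind the regression
#' calibration.
#'
#' @param prescription prescription dose in Gy (default 50, the conventional
#'   25 x 2 Gy post-mastectomy regimen).
#' @param kind \code{"linear"} (dose = prescription - rate * distance) or
#'   \code{"exponential"} (dose = prescription * 2^(-distance / half_distance)).
#' @param rate falloff in Gy/mm for the linear kind (>= 0; 0 gives a uniform
#'   field).
#' @param half_distance mm over which dose halves, for the exponential kind.
#' @param noise_sd additive Gaussian noise on out-of-target dose, Gy.
#' @param seed integer seed for the noise.
#' @return An object of class \code{dose_model}.
#' @export
dose_model <- function(prescription = 50, kind = c("linear", "exponential"),
                       rate = 0.9, half_distance = 15, noise_sd = 0,
                       seed = 1L) {
  kind <- match.arg(kind)
  if (!is.finite(prescription) || prescription <= 0)
    stop("`prescription` must be a positive dose in Gy", call. = FALSE)
  if (kind == "linear" && (!is.finite(rate) || rate < 0))
    stop("`rate` must be a non-negative falloff in Gy/mm", call. = FALSE)
  if (kind == "exponential" && (!is.finite(half_distance) || half_distance <= 0))
    stop("`half_distance` must be a positive length in mm", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be a non-negative dose in Gy", call. = FALSE)
  structure(list(prescription = prescription, kind = kind, rate = rate,
                 half_distance = half_distance, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "dose_model")
}

# evaluate the noise-free falloff at signed distance d (vectorized)
falloff_dose <- function(model, d) {
  base <- if (model$kind == "linear") {
    model$prescription - model$rate * pmax(d, 0)
  } else {
    model$prescription * 2^(-pmax(d, 0) / model$half_distance)
  }
  pmax(base, 0)
}

#' Generate a synthetic thorax phantom
#'
#' Deterministic given the spec (including its seed): builds two ellipsoidal
#' lungs, a spherical heart left of midline (carved out of the lungs), and a
#' chest-wall target slab on the treated side — the set of voxels whose
#' distance to the ipsilateral lung lies in
#' \code{[ptv_lung_gap, ptv_lung_gap + thickness]}, restricted to the
#' anterolateral sector and kept at least \code{ptv_heart_gap} from the heart
#' — plus a supraclavicular block when requested. The stated gaps are realized
#' within one voxel wherever the corresponding structure is the limiting one.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return A list with \code{structure_mask} elements \code{ptv},
#'   \code{heart}, \code{lungs} (both), \code{lung_ipsi},
#'   \code{lung_contra}, and the \code{spec}.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid
  side <- if (spec$laterality == "left") 1 else -1
  j <- with_seed(spec$seed, stats::runif(10, -1, 1))

  semi_i <- spec$lung_semiaxes_mm * (1 + 0.05 * j[1:3])
  semi_c <- spec$lung_semiaxes_mm * (1 + 0.05 * j[4:6])
  c_lung_i <- c(side * 60, -10, 0) + c(2 * j[7], 2 * j[8], 0)
  c_lung_c <- c(-side * 60, -10, 0)
  c_heart <- c(18, 10, -18) + c(2 * j[9], 2 * j[10], 0)
  r_heart <- spec$heart_radius_mm

  lo <- g$origin + g$spacing
  hi <- g$origin + g$shape * g$spacing - g$spacing
  check_fit <- function(center, semi, what) {
    if (any(center - semi < lo) || any(center + semi > hi))
      stop(sprintf("%s (extent %s) exceeds the grid; enlarge the grid or shrink the structure",
                   what, paste(sprintf("%.0f", semi), collapse = "x")),
           call. = FALSE)
  }
  check_fit(c_lung_i, semi_i, "ipsilateral lung")
  check_fit(c_lung_c, semi_c, "contralateral lung")
  check_fit(c_heart, rep(r_heart, 3), "heart")

  heart_v <- ellipsoid_voxels(g, c_heart, rep(r_heart, 3))
  lung_i_v <- ellipsoid_voxels(g, c_lung_i, semi_i)
  lung_c_v <- ellipsoid_voxels(g, c_lung_c, semi_c)
  # lungs wrap the heart anatomically; carve it (plus a 3 mm pericardial
  # margin) out so structures stay disjoint
  not_heart <- !ellipsoid_voxels(g, c_heart, rep(r_heart + 3, 3))
  lung_i_v <- lung_i_v & not_heart
  lung_c_v <- lung_c_v & not_heart

  lung_ipsi <- structure_mask(lung_i_v, g, label = sprintf("Lung_%s", toupper(substr(spec$laterality, 1, 1))))
  sd_lung <- signed_distance_field(lung_ipsi)$values

  cc <- voxel_centers(g)
  dist_heart <- sqrt((cc[, 1] - c_heart[1])^2 + (cc[, 2] - c_heart[2])^2 +
                     (cc[, 3] - c_heart[3])^2) - r_heart
  shell <- sd_lung >= spec$ptv_lung_gap_mm &
           sd_lung <= spec$ptv_lung_gap_mm + spec$chestwall_thickness_mm
  sector <- (side * (cc[, 1] - c_lung_i[1]) + (cc[, 2] - c_lung_i[2])) >= 0
  zband <- abs(cc[, 3] - c_lung_i[3]) <= 0.7 * semi_i[3]
  # implicit body contour: the chest wall cannot extend beyond the skin
  body <- (cc[, 1] / 112)^2 + (cc[, 2] / 112)^2 <= 1
  ptv_v <- shell & array(sector & zband & body &
                           dist_heart >= spec$ptv_heart_gap_mm,
                         dim = g$shape)
  if (spec$include_supraclavicular) {
    z0 <- c_lung_i[3] + 0.75 * semi_i[3]
    block <- abs(cc[, 1] - side * 45) <= 25 & cc[, 2] >= 0 & cc[, 2] <= 40 &
             cc[, 3] >= z0 & cc[, 3] <= min(z0 + 28, hi[3]) & body
    ptv_v <- ptv_v | (array(block & dist_heart >= spec$ptv_heart_gap_mm,
                            dim = g$shape) &
                      sd_lung >= spec$ptv_lung_gap_mm)
  }
  ptv <- structure_mask(ptv_v, g, label = "PTV")

  edge <- array(FALSE, g$shape)
  edge[c(1, g$shape[1]), , ] <- TRUE
  edge[, c(1, g$shape[2]), ] <- TRUE
  edge[, , c(1, g$shape[3])] <- TRUE
  if (any(ptv_v & edge))
    stop("PTV reaches the grid boundary; enlarge the grid", call. = FALSE)

  list(ptv = ptv,
       heart = structure_mask(heart_v, g, label = "Heart"),
       lungs = structure_mask(lung_i_v | lung_c_v, g, label = "Lungs"),
       lung_ipsi = lung_ipsi,
       lung_contra = structure_mask(lung_c_v, g, label = "Lung_contra"),
       spec = spec)
}

#' Generate a parametric dose field for a phantom
#'
#' @param phantom result of \code{\link{generate_phantom}}.
#' @param model a \code{\link{dose_model}}.
#' @param sdf optional precomputed signed distance field of the phantom's
#'   target (saves the transform when already available).
#' @return A \code{\link{scalar_field}} of dose in Gy: prescription inside the
#'   target, \code{falloff(distance) + noise} outside, truncated at 0.
#' @export
generate_dose <- function(phantom, model, sdf = NULL) {
  stopifnot(inherits(model, "dose_model"))
  if (is.null(sdf)) sdf <- signed_distance_field(phantom$ptv)
  d <- sdf$values
  vals <- falloff_dose(model, d)
  vals[d <= 0] <- model$prescription
  if (model$noise_sd > 0) {
    noise <- with_seed(model$seed,
                       stats::rnorm(length(vals), sd = model$noise_sd))
    noise[d <= 0] <- 0
    vals <- pmax(vals + array(noise, dim = dim(vals)), 0)
  }
  scalar_field(vals, phantom$ptv$geometry, unit = "Gy")
}

# standard volume levels per organ: lung D50/D35/D25, heart D10/D5
standard_x_levels <- function(organ) {
  switch(organ, lung = c(50, 35, 25), heart = c(10, 5),
         stop(sprintf("no standard volume levels for organ '%s'", organ),
              call. = FALSE))
}

#' Extract (L_x, D_x) metric pairs from one phantom plan
#'
#' Computes the OVH and DVH of each organ against the phantom's target and
#' reads off the standard metric pairs (lung 50/35/25, heart 10/5 for
#' left-sided cases).
#'
#' @param phantom result of \code{\link{generate_phantom}}.
#' @param dose a dose \code{\link{scalar_field}} on the phantom grid.
#' @param bin_width_mm OVH distance bin (mm). The default is much finer than
#'   the 1 mm curve-export default: voxel distances concentrate on lattice
#'   values, and the quantile read-off must resolve those atoms for the
#'   extracted L_x to be accurate to a few hundredths of a mm.
#' @param bin_width_gy DVH dose bin (Gy).
#' @return A data frame with columns \code{organ}, \code{x}, \code{l_mm},
#'   \code{d_gy}.
#' @export
phantom_metrics <- function(phantom, dose, bin_width_mm = 0.05,
                            bin_width_gy = 0.02) {
  sdf <- signed_distance_field(phantom$ptv)
  organs <- list(lung = phantom$lung_ipsi)
  if (phantom$spec$laterality == "left") organs$heart <- phantom$heart
  do.call(rbind, lapply(names(organs), function(org) {
    ovh <- compute_ovh(organs[[org]], phantom$ptv, bin_width = bin_width_mm,
                       sdf = sdf)
    dvh <- compute_dvh(dose, organs[[org]], bin_width = bin_width_gy)
    xs <- standard_x_levels(org)
    data.frame(organ = org, x = xs, l_mm = l_x(ovh, xs), d_gy = d_x(dvh, xs))
  }))
}

#' Generate a whole synthetic cohort with a known geometry-dose law
#'
#' Draws \code{n} phantoms whose anatomical parameters are sampled uniformly
#' from the given ranges, computes each patient's OVH/DVH metric pairs under
#' the shared dose model, and returns the long-format cohort table. With a
#' linear noise-free falloff the induced law is exactly
#' \code{D_x = prescription - rate * L_x}, so the regression calibration has
#' analytic ground truth.
#'
#' @param n number of patients (>= 1).
#' @param cohort cohort key; sets laterality and plan type.
#' @param spec_ranges named list of \code{c(min, max)} sampling intervals for
#'   \code{chestwall_thickness_mm}, \code{heart_radius_mm},
#'   \code{lung_scale} (multiplier on the default lung semiaxes),
#'   \code{ptv_lung_gap_mm}, \code{ptv_heart_gap_mm}; missing entries use
#'   defaults spanning realistic adult variability.
#' @param model a \code{\link{dose_model}} shared by the cohort.
#' @param seed master seed; every per-patient seed derives from it.
#' @param grid grid geometry for all phantoms.
#' @param out_dir optional directory: writes \code{cohort.csv} and
#'   \code{manifest.json} (all seeds and parameters), plus per-patient NIfTI
#'   masks and dose when \code{write_volumes = TRUE}.
#' @param write_volumes write per-patient volumes under \code{out_dir}.
#' @return The cohort data frame (\code{patient_id, cohort, organ, x, l_mm,
#'   d_gy}), invisibly carrying the sampled parameters as attribute
#'   \code{"params"}.
#' @export
generate_cohort <- function(n, cohort = "left_pmrmrt",
                            spec_ranges = list(), model = dose_model(),
                            seed = 1L,
                            grid = grid_geometry(c(96, 96, 64), c(2.5, 2.5, 2.5)),
                            out_dir = NULL, write_volumes = FALSE) {
  if (!is.numeric(n) || n < 1) stop("`n` must be at least 1", call. = FALSE)
  cohort <- match.arg(cohort, ovhplan_cohorts)
  laterality <- if (grepl("^left", cohort)) "left" else "right"
  plan_type <- if (grepl("pmrmrt$", cohort)) "pmrmrt" else "bcrt"
  defaults <- list(chestwall_thickness_mm = c(10, 20),
                   heart_radius_mm = c(25, 35),
                   lung_scale = c(0.85, 1.15),
                   ptv_lung_gap_mm = c(2, 6),
                   ptv_heart_gap_mm = c(5, 25))
  ranges <- utils::modifyList(defaults, spec_ranges)
  draw <- function(u, key) ranges[[key]][1] + u * diff(ranges[[key]])
  u <- with_seed(seed, matrix(stats::runif(n * 5), nrow = n))
  params <- data.frame(
    patient_id = sprintf("%s_%03d", cohort, seq_len(n)),
    chestwall_thickness_mm = draw(u[, 1], "chestwall_thickness_mm"),
    heart_radius_mm = draw(u[, 2], "heart_radius_mm"),
    lung_scale = draw(u[, 3], "lung_scale"),
    ptv_lung_gap_mm = draw(u[, 4], "ptv_lung_gap_mm"),
    ptv_heart_gap_mm = draw(u[, 5], "ptv_heart_gap_mm"),
    phantom_seed = seed + seq_len(n),
    noise_seed = seed + 100000L + seq_len(n))
  records <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- phantom_spec(laterality = laterality, plan_type = plan_type,
                         grid = grid,
                         chestwall_thickness_mm = params$chestwall_thickness_mm[i],
                         heart_radius_mm = params$heart_radius_mm[i],
                         lung_semiaxes_mm = c(38, 52, 62) * params$lung_scale[i],
                         ptv_lung_gap_mm = params$ptv_lung_gap_mm[i],
                         ptv_heart_gap_mm = params$ptv_heart_gap_mm[i],
                         seed = params$phantom_seed[i])
    ph <- generate_phantom(spec)
    m <- model; m$seed <- params$noise_seed[i]
    sdf <- signed_distance_field(ph$ptv)
    dose <- generate_dose(ph, m, sdf = sdf)
    met <- phantom_metrics(ph, dose)
    met$patient_id <- params$patient_id[i]
    met$cohort <- cohort
    records[[i]] <- met[, c("patient_id", "cohort", "organ", "x", "l_mm", "d_gy")]
    if (!is.null(out_dir) && write_volumes) {
      pd <- file.path(out_dir, params$patient_id[i])
      dir.create(pd, recursive = TRUE, showWarnings = FALSE)
      write_volume(ph$ptv, file.path(pd, "ptv.nii.gz"))
      write_volume(ph$heart, file.path(pd, "heart.nii.gz"))
      write_volume(ph$lung_ipsi, file.path(pd, "lung_ipsi.nii.gz"))
      write_volume(dose, file.path(pd, "dose.nii.gz"))
    }
  }
  tab <- do.call(rbind, records)
  rownames(tab) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort_csv(tab, file.path(out_dir, "cohort.csv"))
    manifest <- list(n = n, cohort = cohort, seed = seed,
                     grid = list(shape = grid$shape, spacing = grid$spacing,
                                 origin = grid$origin),
                     dose_model = unclass(model), ranges = ranges,
                     params = params)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  attr(tab, "params") <- params
  tab
}
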