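ovhplan_cohorts <- c("left_pmrmrt", "right_pmrmrt", "left_bcrt", "right_bcrt")

#' Linear L_x to D_x regression model
#'
#' A per-cohort simple linear model \code{D_x = slope * L_x + intercept}
#' linking the OVH expansion distance L_x (mm) of an organ to the achievable
#' dose level D_x (Gy), with Pearson-based goodness of fit. Models are fitted
#' strictly within one cohort (laterality x treatment modality): geometry-dose
#' relationships differ systematically between the four strata, so cohorts are
#' never pooled.
#'
#' @param organ organ name (e.g. "lung", "heart").
#' @param x percent volume the metric pair refers to.
#' @param cohort one of \code{"left_pmrmrt"}, \code{"right_pmrmrt"},
#'   \code{"left_bcrt"}, \code{"right_bcrt"}.
#' @param slope Gy per mm.
#' @param intercept Gy.
#' @param r_squared squared Pearson correlation in [0, 1].
#' @param p_value two-tailed p for the zero-slope t test (NA for published
#'   models that only report a bound).
#' @param n sample size used for the fit (>= 3).
#' @param l_range observed L_x range of the training data (mm), used to flag
#'   extrapolation at prediction time; may be NULL.
#' @param p_bound printed p bound for published models (e.g. "<0.001").
#' @param source \code{"fitted"} or \code{"published"}.
#' @param fit_date ISO date string recorded at fit time.
#' @return An object of class \code{regression_model}.
#' @export
regression_model <- function(organ, x, cohort, slope, intercept, r_squared,
                             p_value, n, l_range = NULL, p_bound = NA_character_,
                             source = "fitted", fit_date = NA_character_) {
  cohort <- match.arg(cohort, ovhplan_cohorts)
  if (!is.numeric(n) || n < 3)
    stop("a regression model needs n >= 3 observations", call. = FALSE)
  if (!is.finite(r_squared) || r_squared < -1e-9 || r_squared > 1 + 1e-9)
    stop("r_squared must lie in [0, 1]", call. = FALSE)
  if (source == "fitted" &&
      (!is.finite(p_value) || p_value < 0 || p_value > 1))
    stop("p_value must lie in [0, 1] for fitted models", call. = FALSE)
  structure(list(organ = organ, x = as.numeric(x), cohort = cohort,
                 slope = as.numeric(slope), intercept = as.numeric(intercept),
                 r_squared = min(max(as.numeric(r_squared), 0), 1),
                 p_value = as.numeric(p_value), n = as.integer(n),
                 l_range = if (is.null(l_range)) NULL else as.numeric(l_range),
                 p_bound = p_bound, source = source, fit_date = fit_date),
            class = "regression_model")
}

#' @export
print.regression_model <- function(x, ...) {
  pv <- if (is.na(x$p_value)) x$p_bound else sprintf("%.3g", x$p_value)
  cat(sprintf("<regression_model> [%s] %s D%g = %+.3g L%g %+.3g  (r2 %.2f, p %s, n %d)\n",
              x$cohort, x$organ, x$x, x$slope, x$x, x$intercept,
              x$r_squared, pv, x$n))
  invisible(x)
}

#' Fit a linear L_x to D_x model for one cohort
#'
#' Ordinary least squares on (L_x, D_x) pairs; \code{r_squared} is the squared
#' Pearson correlation (identical to OLS R-squared for simple regression) and
#' \code{p_value} is the two-tailed test of zero slope on the t distribution
#' with n - 2 degrees of freedom.
#'
#' @param pairs a data frame (or list) with numeric columns/elements
#'   \code{l_mm} and \code{d_gy}.
#' @inheritParams regression_model
#' @return A \code{\link{regression_model}}.
#' @export
fit_model <- function(pairs, organ, x, cohort) {
  l <- as.numeric(pairs$l_mm); d <- as.numeric(pairs$d_gy)
  if (length(l) != length(d))
    stop("`pairs` must provide equal-length l_mm and d_gy", call. = FALSE)
  keep <- is.finite(l) & is.finite(d)
  l <- l[keep]; d <- d[keep]
  n <- length(l)
  if (n < 3)
    stop(sprintf("cannot fit a line through %d point(s); need n >= 3", n),
         call. = FALSE)
  if (stats::var(l) == 0)
    stop("degenerate input: all L values identical, the slope is unidentifiable",
         call. = FALSE)
  slope <- stats::cov(l, d) / stats::var(l)
  intercept <- mean(d) - slope * mean(l)
  r <- if (stats::sd(d) == 0) 0 else stats::cov(l, d) / (stats::sd(l) * stats::sd(d))
  r2 <- min(r^2, 1)
  p <- if (r2 >= 1 - 1e-15) 0
       else 2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r2))), df = n - 2)
  regression_model(organ = organ, x = x, cohort = cohort, slope = slope,
                   intercept = intercept, r_squared = r2, p_value = p, n = n,
                   l_range = range(l), source = "fitted",
                   fit_date = format(Sys.Date()))
}

#' Predict an achievable D_x from L_x
#'
#' Evaluates \code{slope * l_mm + intercept} and clamps the result below at
#' 0 Gy (a dose constraint can never be negative). Flags report when clamping
#' occurred and when \code{l_mm} lies outside the model's fitted L range
#' (extrapolation); published models carry no range, so their extrapolation
#' flag is \code{NA}.
#'
#' @param model a \code{\link{regression_model}}.
#' @param l_mm L_x value(s) in mm.
#' @return An object of class \code{dx_prediction}: list with numeric
#'   \code{dose_gy} and logical \code{clamped}, \code{extrapolated}
#'   (all parallel to \code{l_mm}).
#' @export
predict_dx <- function(model, l_mm) {
  stopifnot(inherits(model, "regression_model"))
  if (any(!is.finite(l_mm)))
    stop("`l_mm` must be finite", call. = FALSE)
  raw <- model$slope * l_mm + model$intercept
  clamped <- raw < 0
  extrapolated <- if (is.null(model$l_range)) rep(NA, length(l_mm))
                  else l_mm < model$l_range[1] | l_mm > model$l_range[2]
  if (any(clamped))
    warning(sprintf("%d prediction(s) clamped at 0 Gy (L outside the model's linear regime)",
                    sum(clamped)), call. = FALSE)
  if (isTRUE(any(extrapolated)))
    warning(sprintf("%d prediction(s) extrapolate beyond the fitted L range [%.1f, %.1f] mm",
                    sum(extrapolated), model$l_range[1], model$l_range[2]),
            call. = FALSE)
  structure(list(dose_gy = pmax(raw, 0), clamped = clamped,
                 extrapolated = extrapolated, organ = model$organ,
                 x = model$x, cohort = model$cohort),
            class = "dx_prediction")
}

#' @export
print.dx_prediction <- function(x, ...) {
  cat(sprintf("<dx_prediction> %s D%g [%s]: %s Gy\n", x$organ, x$x, x$cohort,
              paste(sprintf("%.2f", x$dose_gy), collapse = ", ")))
  invisible(x)
}

#' Published reference models for the four breast-radiotherapy cohorts
#'
#' Returns the shipped cohort calibrations linking L_x (mm) to achievable D_x
#' (Gy), as fitted on a 322-patient institutional database stratified by
#' laterality and modality. Left-sided cohorts carry ipsilateral-lung models
#' (D50/D35/D25) plus heart models (D10/D5); right-sided cohorts carry lung
#' models only, since the heart is distant from right-sided targets. The
#' coefficients, r-squared values and p bounds are reproduced verbatim from
#' the packaged JSON asset.
#'
#' @param cohort one of \code{"left_pmrmrt"}, \code{"right_pmrmrt"},
#'   \code{"left_bcrt"}, \code{"right_bcrt"}.
#' @return A list of \code{\link{regression_model}} objects.
#' @examples
#' m <- bundled_models("left_pmrmrt")
#' vapply(m, function(mm) mm$slope, numeric(1))
#' @export
bundled_models <- function(cohort) {
  cohort <- match.arg(cohort, ovhplan_cohorts)
  path <- system.file("extdata", "published_models.json", package = "ovhplan",
                      mustWork = TRUE)
  all <- read_models_json(path)
  all[vapply(all, function(m) m$cohort == cohort, logical(1))]
}

#' Read/write regression models as JSON
#'
#' Models round-trip losslessly: numeric fields are serialized at full
#' precision.
#'
#' @param models a list of \code{\link{regression_model}} objects (or one).
#' @param path JSON file path.
#' @export
write_models_json <- function(models, path) {
  if (inherits(models, "regression_model")) models <- list(models)
  recs <- lapply(models, function(m) {
    r <- unclass(m)
    r[!vapply(r, is.null, logical(1))]
  })
  # I(17) significant digits: doubles survive the text round trip bit-exactly
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_models_json
#' @export
read_models_json <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read models: '%s' does not exist", path), call. = FALSE)
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, function(r) {
    regression_model(organ = r$organ, x = r$x, cohort = r$cohort,
                     slope = r$slope, intercept = r$intercept,
                     r_squared = r$r_squared,
                     p_value = if (is.null(r$p_value)) NA_real_ else r$p_value,
                     n = r$n,
                     l_range = if (is.null(r$l_range)) NULL else unlist(r$l_range),
                     p_bound = if (is.null(r$p_bound)) NA_character_ else r$p_bound,
                     source = if (is.null(r$source)) "fitted" else r$source,
                     fit_date = if (is.null(r$fit_date)) NA_character_ else r$fit_date)
  })
}

#' Read/write cohort metric tables as CSV
#'
#' Long-format table with columns \code{patient_id, cohort, organ, x, l_mm,
#' d_gy}: one row per patient and metric pair.
#'
#' @param records a data frame in the cohort layout.
#' @param path CSV file path.
#' @export
write_cohort_csv <- function(records, path) {
  need <- c("patient_id", "cohort", "organ", "x", "l_mm", "d_gy")
  if (!all(need %in% names(records)))
    stop(sprintf("cohort table must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  utils::write.csv(records[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read cohort table: '%s' does not exist", path),
         call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "cohort", "organ", "x", "l_mm", "d_gy")
  if (!all(need %in% names(tab)))
    stop(sprintf("cohort table must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  if (any(tab$l_mm < 0, na.rm = TRUE))
    warning("cohort table contains negative L values (organ voxels inside the target)",
            call. = FALSE)
  if (any(tab$d_gy < 0, na.rm = TRUE))
    stop("cohort table contains negative doses", call. = FALSE)
  tab
}

#' Fit models for every (organ, x) metric in a single-cohort table
#'
#' @param records cohort table as from \code{\link{read_cohort_csv}} or
#'   \code{\link{generate_cohort}}; must contain exactly one cohort.
#' @return A list of \code{\link{regression_model}} objects, one per
#'   (organ, x) pair present.
#' @export
fit_cohort_models <- function(records) {
  cohorts <- unique(records$cohort)
  if (length(cohorts) != 1L)
    stop(sprintf("cohort table mixes %d cohorts (%s); fit each stratum separately",
                 length(cohorts), paste(cohorts, collapse = ", ")), call. = FALSE)
  keys <- unique(records[, c("organ", "x")])
  keys <- keys[order(keys$organ, -keys$x), ]
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- records[records$organ == keys$organ[i] & records$x == keys$x[i], ]
    fit_model(sub, organ = keys$organ[i], x = keys$x[i], cohort = cohorts)
  })
}
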