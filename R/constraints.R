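#' Clinical dose-volume ceilings per cohort
#'
#' The institutional hard limits that a predicted constraint may tighten but
#' never relax: ipsilateral lung V5Gy <= 50%, V10Gy <= 35%, V20Gy <= 25% for
#' every cohort, and for left-sided cohorts additionally heart V20Gy <= 10%,
#' V40Gy <= 5% and a mean-heart-dose cap. The printed mean-dose limit is a
#' 6-8 Gy range; the lenient bound (8 Gy) is used as the default cap.
#'
#' @param cohort one of the four cohort keys (see
#'   \code{\link{regression_model}}).
#' @return A data frame with columns \code{organ}, \code{metric_kind}
#'   (\code{"V_at_dose"} or \code{"D_mean_cap"}), \code{dose_gy},
#'   \code{volume_pct} (NA for mean-dose caps).
#' @export
clinical_limits <- function(cohort) {
  cohort <- match.arg(cohort, ovhplan_cohorts)
  lung <- data.frame(organ = "lung", metric_kind = "V_at_dose",
                     dose_gy = c(5, 10, 20), volume_pct = c(50, 35, 25))
  if (!grepl("^left", cohort)) return(lung)
  heart <- data.frame(organ = "heart",
                      metric_kind = c("V_at_dose", "V_at_dose", "D_mean_cap"),
                      dose_gy = c(20, 40, 8), volume_pct = c(10, 5, NA))
  rbind(lung, heart)
}

#' Build an optimization constraint set from predicted D_x values
#'
#' Each predicted D_x becomes an overdose-style objective
#' \code{V_{D} <= x\%}, where the constraint dose D is the predicted D_x capped
#' by the clinical ceiling for the same organ and volume level: a generated
#' constraint is never laxer than the clinical limit. Mean-dose caps have no
#' L_x-based predictor, so they are emitted directly from the ceilings.
#' Predictions for a volume level without a ceiling are kept and flagged
#' \code{no_ceiling}; predictions clamped to 0 Gy are flagged
#' \code{degenerate}.
#'
#' @param predictions data frame with columns \code{organ}, \code{x} (percent
#'   volume) and \code{dose_gy} (predicted D_x, Gy), e.g. assembled from
#'   \code{\link{predict_dx}} results.
#' @param cohort cohort key, used for default ceilings and recorded in the set.
#' @param limits ceiling table as from \code{\link{clinical_limits}}.
#' @param patient_id identifier recorded in the set.
#' @param provenance character vector of model identifiers used.
#' @return An object of class \code{constraint_set} with an \code{entries}
#'   data frame (\code{organ}, \code{metric_kind}, \code{dose_gy},
#'   \code{volume_pct}, \code{relation}, \code{ceiling_applied},
#'   \code{no_ceiling}, \code{degenerate}), sorted by organ then volume
#'   descending.
#' @export
make_constraints <- function(predictions, cohort,
                             limits = clinical_limits(cohort),
                             patient_id = NA_character_,
                             provenance = character()) {
  cohort <- match.arg(cohort, ovhplan_cohorts)
  need <- c("organ", "x", "dose_gy")
  if (!is.data.frame(predictions) || nrow(predictions) == 0 ||
      !all(need %in% names(predictions)))
    stop("`predictions` must be a non-empty data frame with columns organ, x, dose_gy",
         call. = FALSE)
  if (any(predictions$dose_gy < 0) || any(predictions$x <= 0 | predictions$x > 100))
    stop("predictions must have dose_gy >= 0 and x in (0, 100]", call. = FALSE)
  vlim <- limits[limits$metric_kind == "V_at_dose", , drop = FALSE]
  rows <- lapply(seq_len(nrow(predictions)), function(i) {
    p <- predictions[i, ]
    hit <- vlim$organ == p$organ & abs(vlim$volume_pct - p$x) < 1e-9
    ceiling_dose <- if (any(hit)) vlim$dose_gy[which(hit)[1]] else NA_real_
    dose <- if (is.na(ceiling_dose)) p$dose_gy else min(p$dose_gy, ceiling_dose)
    data.frame(organ = p$organ, metric_kind = "V_at_dose", dose_gy = dose,
               volume_pct = p$x, relation = "<=",
               ceiling_applied = !is.na(ceiling_dose) && ceiling_dose < p$dose_gy,
               no_ceiling = is.na(ceiling_dose),
               degenerate = dose <= 0)
  })
  entries <- do.call(rbind, rows)
  caps <- limits[limits$metric_kind == "D_mean_cap", , drop = FALSE]
  if (nrow(caps) > 0) {
    entries <- rbind(entries,
                     data.frame(organ = caps$organ, metric_kind = "D_mean_cap",
                                dose_gy = caps$dose_gy, volume_pct = NA_real_,
                                relation = "<=", ceiling_applied = FALSE,
                                no_ceiling = FALSE, degenerate = FALSE))
  }
  entries <- entries[order(entries$organ, -xtfrm(replace(entries$volume_pct,
                                                         is.na(entries$volume_pct),
                                                         -Inf))), ]
  rownames(entries) <- NULL
  structure(list(patient_id = patient_id, cohort = cohort, entries = entries,
                 provenance = provenance),
            class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  cat(sprintf("<constraint_set> patient %s [%s], %d entries\n",
              x$patient_id, x$cohort, nrow(x$entries)))
  for (i in seq_len(nrow(x$entries))) {
    e <- x$entries[i, ]
    if (e$metric_kind == "V_at_dose")
      cat(sprintf("  %-6s V_%.2fGy <= %g%%%s\n", e$organ, e$dose_gy,
                  e$volume_pct,
                  if (e$degenerate) "  [degenerate]" else if (e$no_ceiling) "  [no ceiling]" else ""))
    else
      cat(sprintf("  %-6s D_mean <= %g Gy\n", e$organ, e$dose_gy))
  }
  invisible(x)
}

#' Read/write constraint sets (JSON canonical, CSV template dialect)
#'
#' The CSV template is a flat \code{organ,type,dose_gy,volume_pct} table meant
#' for transcription into a treatment planning system.
#'
#' @param cs a \code{constraint_set}.
#' @param path destination file.
#' @export
write_constraints_json <- function(cs, path) {
  stopifnot(inherits(cs, "constraint_set"))
  jsonlite::write_json(unclass(cs), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_constraints_json
#' @export
read_constraints_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$entries <- as.data.frame(x$entries)
  structure(x[c("patient_id", "cohort", "entries", "provenance")],
            class = "constraint_set")
}

#' @rdname write_constraints_json
#' @export
write_constraints_csv <- function(cs, path) {
  stopifnot(inherits(cs, "constraint_set"))
  out <- data.frame(organ = cs$entries$organ, type = cs$entries$metric_kind,
                    dose_gy = cs$entries$dose_gy,
                    volume_pct = cs$entries$volume_pct)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Percent dose reduction of an automated plan versus a manual plan
#'
#' \code{100 * (manual - auto) / manual}; negative when the automated plan is
#' worse. Vectorized.
#'
#' @param manual manual-plan dose metric(s), Gy, strictly positive.
#' @param auto automated-plan dose metric(s), Gy.
#' @return Percent reduction(s).
#' @examples
#' percent_reduction(16.17, 13.65)  # 15.6% heart D10 sparing
#' @export
percent_reduction <- function(manual, auto) {
  if (any(!is.finite(manual)) || any(manual <= 0))
    stop("`manual` must be strictly positive to define a percent reduction",
         call. = FALSE)
  100 * (manual - auto) / manual
}

#' Compare a dose metric between manual and automated cohorts
#'
#' Computes per-arm mean and standard deviation, the percent reduction of the
#' means, and a two-tailed t-test p-value (paired by default, matching how
#' re-planned cases are compared against their own manual plans; Welch
#' otherwise). The paired statistic is \code{mean(diff) / (sd(diff)/sqrt(n))}
#' on n - 1 degrees of freedom; when all differences are identical the p-value
#' degenerates to 1 for a zero shift and 0 for a nonzero shift.
#'
#' @param manual,auto numeric vectors of per-patient metric values.
#' @param paired logical; requires equal lengths when TRUE.
#' @param metric optional label (e.g. "heart D10") carried in the result.
#' @return An object of class \code{cohort_comparison}.
#' @export
compare_cohorts <- function(manual, auto, paired = TRUE, metric = "metric") {
  manual <- as.numeric(manual); auto <- as.numeric(auto)
  if (length(manual) < 2 || length(auto) < 2)
    stop("need at least two patients per arm", call. = FALSE)
  if (paired && length(manual) != length(auto))
    stop(sprintf("paired comparison needs equal lengths (got %d vs %d)",
                 length(manual), length(auto)), call. = FALSE)
  if (paired) {
    dif <- manual - auto
    n <- length(dif)
    if (stats::sd(dif) == 0) {
      p <- if (abs(mean(dif)) < 1e-12) 1 else 0
    } else {
      tstat <- mean(dif) / (stats::sd(dif) / sqrt(n))
      p <- 2 * stats::pt(-abs(tstat), df = n - 1)
    }
  } else {
    v1 <- stats::var(manual) / length(manual)
    v2 <- stats::var(auto) / length(auto)
    if (v1 + v2 == 0) {
      p <- if (abs(mean(manual) - mean(auto)) < 1e-12) 1 else 0
    } else {
      tstat <- (mean(manual) - mean(auto)) / sqrt(v1 + v2)
      df <- (v1 + v2)^2 / (v1^2 / (length(manual) - 1) + v2^2 / (length(auto) - 1))
      p <- 2 * stats::pt(-abs(tstat), df = df)
    }
  }
  structure(list(metric = metric,
                 manual_mean = mean(manual), manual_sd = stats::sd(manual),
                 auto_mean = mean(auto), auto_sd = stats::sd(auto),
                 percent_reduction = if (mean(manual) > 0)
                   percent_reduction(mean(manual), mean(auto)) else NA_real_,
                 p_value = p, n_manual = length(manual), n_auto = length(auto),
                 paired = paired),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("<cohort_comparison> %s: %.2f +/- %.2f -> %.2f +/- %.2f (%.1f%% reduction, p = %.3g)\n",
              x$metric, x$manual_mean, x$manual_sd, x$auto_mean, x$auto_sd,
              x$percent_reduction, x$p_value))
  invisible(x)
}

#' Write a cohort comparison report as CSV
#'
#' One row per metric: manual mean/SD, automated mean/SD, percent reduction
#' (one decimal place, matching conventional reporting) and p-value.
#'
#' @param comparisons a list of \code{cohort_comparison} objects.
#' @param path CSV file path.
#' @export
write_comparison_csv <- function(comparisons, path) {
  if (inherits(comparisons, "cohort_comparison")) comparisons <- list(comparisons)
  tab <- do.call(rbind, lapply(comparisons, function(cc)
    data.frame(metric = cc$metric,
               manual_mean = cc$manual_mean, manual_sd = cc$manual_sd,
               auto_mean = cc$auto_mean, auto_sd = cc$auto_sd,
               percent_reduction = round(cc$percent_reduction, 1),
               p_value = cc$p_value)))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
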