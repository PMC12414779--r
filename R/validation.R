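# Analytical-validation statistics: blank/detection/quantification limits,
# precision profile, overall precision, expanded uncertainty, diagnostic
# cut-offs.

#' Analytical coefficient of variation (percent)
#'
#' `CV_A = 100 * SD / mean` over replicate measurements, with the sample SD
#' (n - 1 denominator — the convention for small replicate counts such as
#' triplicates).
#'
#' @param measurements Numeric vector of >= 2 replicate percentages.
#' @return CV as a percentage.
#' @export
#' @examples
#' compute_cv(c(9, 10, 11)) # 10
compute_cv <- function(measurements) {
  if (length(measurements) < 2) {
    stop("need at least 2 measurements to compute a CV", call. = FALSE)
  }
  m <- mean(measurements)
  if (m <= 0) stop("CV undefined: mean of measurements is not positive",
                   call. = FALSE)
  100 * sd(measurements) / m
}

#' Limit of blank
#'
#' `LOB = mean(blanks) + 1.65 * SD(blanks)` (sample SD): the measurement
#' level below which analyte-free samples fall with ~95% one-sided
#' probability under a normal blank distribution.
#'
#' @param blank_values Numeric vector of >= 2 non-negative blank outputs
#'   (percent).
#' @return List with `lob`, `blank_mean`, `blank_sd`.
#' @export
compute_lob <- function(blank_values) {
  if (length(blank_values) < 2) {
    stop("need at least 2 blank measurements", call. = FALSE)
  }
  if (any(blank_values < 0)) stop("blank values must be >= 0", call. = FALSE)
  m <- mean(blank_values)
  s <- sd(blank_values)
  list(lob = m + 1.65 * s, blank_mean = m, blank_sd = s)
}

#' Lower limit of detection
#'
#' `LLoD = LOB + 1.65 * SD`. The SD is that of the blank replicates (the
#' only replicate SD the 10-blank design yields); pass the SD of a low-level
#' sample instead to follow the guideline alternative.
#'
#' @param lob Limit of blank (percent), >= 0.
#' @param sd Standard deviation (percentage points), >= 0.
#' @return LLoD as a percentage, always >= `lob`.
#' @export
compute_llod <- function(lob, sd) {
  if (lob < 0 || sd < 0) stop("lob and sd must be >= 0", call. = FALSE)
  lob + 1.65 * sd
}

#' Build a per-dilution precision table
#'
#' One row per dilution level with its replicate mean, sample SD and CV_A,
#' sorted by descending nominal fraction.
#'
#' @param series A list of `list(nominal_fraction, measurements)` entries, or
#'   a data.frame with columns `nominal_fraction` and `mast_pct` (rows
#'   grouped by level). Each level needs >= 2 measurements.
#' @return A data.frame of class `precision_table` with columns
#'   `nominal_fraction`, `n`, `mean`, `sd`, `cv_a`.
#' @export
build_precision_table <- function(series) {
  if (is.data.frame(series)) {
    sp <- split(series$mast_pct, series$nominal_fraction)
    series <- Map(function(f, v) list(nominal_fraction = as.numeric(f),
                                      measurements = v),
                  names(sp), sp)
  }
  rows <- lapply(series, function(lv) {
    v <- lv$measurements
    data.frame(nominal_fraction = lv$nominal_fraction,
               n = length(v), mean = mean(v), sd = sd(v),
               cv_a = compute_cv(v))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$nominal_fraction), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("precision_table", "data.frame")
  out
}

#' Overall precision as the root mean square of per-dilution CVs
#'
#' `sqrt(mean(cv_i^2))`; always between min and max of the CVs and at least
#' their arithmetic mean (RMS dominance).
#'
#' @param cv_list Non-empty numeric vector of per-dilution CVs (percent).
#' @return Overall CV_A as a percentage.
#' @export
#' @examples
#' compute_overall_precision(c(3, 4)) # 3.54
compute_overall_precision <- function(cv_list) {
  if (length(cv_list) == 0) stop("need at least one CV", call. = FALSE)
  if (any(cv_list < 0)) stop("CVs must be >= 0", call. = FALSE)
  sqrt(mean(cv_list^2))
}

#' Select the lower limit of quantification from a precision profile
#'
#' The LLoQ is the lowest nominal concentration at or above the LLoD whose
#' replicate CV_A is below `cv_threshold` (default 30%; 35% is an accepted
#' relaxation for rare-event work). Only the selected level's CV is tested.
#' Optionally a linearity (recovery) requirement is added: the level's mean
#' must recover `nominal * [recovery_window]`.
#'
#' @param precision A [build_precision_table()] result.
#' @param llod LLoD in percent.
#' @param cv_threshold CV acceptance threshold in percent (default 30).
#' @param check_linearity If `TRUE`, also require mean/nominal recovery
#'   inside `recovery_window`.
#' @param recovery_window Length-2 proportions, default `c(0.7, 1.3)`.
#' @return List with `lloq` (NA if no level qualifies) and `lloq_cv`.
#' @export
select_lloq <- function(precision, llod, cv_threshold = 30,
                        check_linearity = FALSE,
                        recovery_window = c(0.7, 1.3)) {
  stopifnot(nrow(precision) >= 1)
  asc <- precision[order(precision$nominal_fraction), , drop = FALSE]
  for (i in seq_len(nrow(asc))) {
    f <- asc$nominal_fraction[i]
    if (f < llod) next
    if (asc$cv_a[i] >= cv_threshold) next
    if (check_linearity) {
      rec <- asc$mean[i] / f
      if (rec < recovery_window[1] || rec > recovery_window[2]) next
    }
    return(list(lloq = f, lloq_cv = asc$cv_a[i]))
  }
  list(lloq = NA_real_, lloq_cv = NA_real_)
}

#' Expanded relative measurement uncertainty from overall precision
#'
#' `EMU = k * CV/100` with coverage factor `k = 2` (the standard expanded-
#' uncertainty convention, ~95% coverage). Dimensionless; summaries print it
#' to 2 decimals.
#'
#' @param overall_cv Overall CV_A in percent, >= 0.
#' @param coverage_factor Coverage factor k > 0 (default 2).
#' @return EMU (dimensionless, unrounded).
#' @export
#' @examples
#' round(compute_emu(8.4), 2) # 0.17
compute_emu <- function(overall_cv, coverage_factor = 2) {
  if (overall_cv < 0) stop("overall_cv must be >= 0", call. = FALSE)
  if (coverage_factor <= 0) stop("coverage_factor must be > 0",
                                 call. = FALSE)
  coverage_factor * overall_cv / 100
}

#' Report a measured percentage with its expanded uncertainty
#'
#' Applies the reporting rule `x +/- (x * EMU)`: the half-width of the
#' interval is proportional to the measured value.
#'
#' @param x Measured percentage, >= 0.
#' @param emu Expanded relative uncertainty, >= 0.
#' @return List of class `uncertainty_report` with `x`, `emu`, `half_width`,
#'   `interval` (length 2) and `formatted` ("x ± h%", both to <= 2
#'   decimals).
#' @export
#' @examples
#' report_with_uncertainty(0.3, compute_emu(8.4))$formatted # "0.3 ± 0.05%"
report_with_uncertainty <- function(x, emu) {
  if (x < 0 || emu < 0) stop("x and emu must be >= 0", call. = FALSE)
  h <- x * emu
  structure(list(
    x = x, emu = emu, half_width = h,
    interval = c(x - h, x + h),
    formatted = paste0(format(round(x, 2)), " ± ",
                       format(round(h, 2)), "%")
  ), class = "uncertainty_report")
}

#' @export
print.uncertainty_report <- function(x, ...) {
  cat("<uncertainty_report> ", x$formatted,
      "  (EMU = ", format(round(x$emu, 2)), ")\n", sep = "")
  invisible(x)
}

#' Classify nodal mast-cell infiltration against diagnostic cut-offs
#'
#' Lymph-node infiltration strictly above 0.3% is diagnostic for a
#' metastatic node (histological classes HN2/HN3); strictly above 4% for
#' overt metastasis (HN3). Values exactly at a cut-off stay in the lower
#' category.
#'
#' @param mast_pct Measured nodal infiltration percentage in `[0, 100]`.
#' @param cutoffs Named numeric vector `c(metastatic = 0.3, hn3 = 4)`.
#' @return List of class `nodal_classification` with `mast_pct`, `category`
#'   (one of `below_cutoff`, `metastatic_HN2_HN3`, `HN3`) and `cutoffs`.
#' @export
#' @examples
#' classify_nodal_infiltration(1.0)$category # metastatic_HN2_HN3
classify_nodal_infiltration <- function(mast_pct,
                                        cutoffs = c(metastatic = 0.3,
                                                    hn3 = 4)) {
  if (!is.finite(mast_pct) || mast_pct < 0 || mast_pct > 100) {
    stop("mast_pct must be a percentage in [0, 100]", call. = FALSE)
  }
  category <- if (mast_pct > cutoffs[["hn3"]]) "HN3"
  else if (mast_pct > cutoffs[["metastatic"]]) "metastatic_HN2_HN3"
  else "below_cutoff"
  structure(list(mast_pct = mast_pct, category = category,
                 cutoffs = cutoffs),
            class = "nodal_classification")
}
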