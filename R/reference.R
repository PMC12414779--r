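# Published reference values for the validated canine mast-cell panel,
# bundled so worked examples and desk recomputations (overall precision,
# LLoQ selection, uncertainty reporting) need no external files.

#' Reference analytical-validation values for the mast-cell panel
#'
#' The published validation figures for the flow-cytometric canine
#' mast-cell panel this package models: per-dilution analytical CVs
#' (triplicates) for each matrix, the blank-derived limits (LOB, LLoD), and
#' the Passing-Bablok accuracy estimates with their 95% confidence bounds.
#' These are reference inputs for desk recomputation — e.g. feeding the CV
#' profile to [compute_overall_precision()] or [select_lloq()] — not outputs
#' of this package.
#'
#' @return A list with elements `precision` (data.frame: `matrix`,
#'   `nominal_fraction`, `cv_a`), `limits` (data.frame: `matrix`, `lob`,
#'   `llod`, all percent), and `accuracy` (data.frame: `matrix`,
#'   `intercept`, `intercept_lo`, `intercept_hi`, `slope`, `slope_lo`,
#'   `slope_hi`).
#' @export
#' @examples
#' ref <- reference_validation_values()
#' ln <- subset(ref$precision, matrix == "LN")
#' compute_overall_precision(ln$cv_a) # ~8.4
reference_validation_values <- function() {
  precision <- rbind(
    data.frame(matrix = "PB",
               nominal_fraction = c(10, 7, 5, 3, 2, 1, 0.5, 0.3, 0.1),
               cv_a = c(1.79, 1.65, 4.14, 4.07, 3.71, 4.42, 5.58, 6.14,
                        12.30)),
    data.frame(matrix = "BM",
               nominal_fraction = c(10, 7, 5, 3, 2, 1, 0.5, 0.3, 0.1),
               cv_a = c(2.54, 7.42, 4.62, 4.27, 3.61, 9.83, 11.31, 13.77,
                        13.39)),
    data.frame(matrix = "LN",
               nominal_fraction = c(50, 25, 10, 5, 2, 1, 0.5, 0.3, 0.1),
               cv_a = c(0.57, 8.94, 5.45, 4.07, 9.37, 9.37, 9.99, 11.93,
                        9.50))
  )
  limits <- data.frame(
    matrix = c("PB", "BM", "LN"),
    lob = c(0.007, 0.013, 0.025),
    llod = c(0.010, 0.020, 0.042)
  )
  accuracy <- data.frame(
    matrix = c("PB", "BM", "LN"),
    intercept = c(-0.007, -0.024, 0.009),
    intercept_lo = c(-0.064, -0.137, -0.051),
    intercept_hi = c(0.013, 0.091, 0.687),
    slope = c(0.973, 1.092, 1.4),
    slope_lo = c(0.881, 0.917, 1.167),
    slope_hi = c(1, 1.205, 1.504)
  )
  list(precision = precision, limits = limits, accuracy = accuracy)
}
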