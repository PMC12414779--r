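# End-to-end validation pipeline: simulate -> gate -> validate -> report.

#' Run a full analytical-validation study on simulated data
#'
#' Generates the blank set and the spike-in dilution series for one matrix,
#' gates every tube, and assembles the complete validation statistics:
#' detection limits (LOB, LLoD, LLoQ), the per-dilution precision profile
#' and overall precision, a Passing-Bablok accuracy fit of measured against
#' nominal percentages, the expanded measurement uncertainty, and example
#' uncertainty reports at the diagnostic nodal cut-offs (0.3% and 4%). All
#' randomness flows from `design$rng_seed`; re-running with identical inputs
#' reproduces the report exactly.
#'
#' Tubes are simulated and gated one at a time, so memory stays bounded even
#' for 500,000-event acquisitions.
#'
#' @param design An [experiment_design()].
#' @param profile A [matrix_profile()]; default the matrix's
#'   [default_matrix_profile()].
#' @param mast_spec Spiked population, default [default_mast_spec()].
#' @param gates A [gate_config()], default [default_gate_config()].
#' @param noise_cv Per-repeat multiplicative spike noise CV (fraction),
#'   default 0.
#' @param pb_repeat Which repeat provides the accuracy points (one
#'   measurement per level); default 1.
#' @param verbose Emit one log line per tube (matrix, level, repeat, event
#'   counts).
#' @return A list of class `validation_report`.
#' @export
run_validation <- function(design,
                           profile = default_matrix_profile(design$matrix),
                           mast_spec = default_mast_spec(),
                           gates = default_gate_config(),
                           noise_cv = 0,
                           pb_repeat = 1L,
                           verbose = FALSE) {
  stopifnot(inherits(design, "experiment_design"))
  tubes <- dilution_series_plan(design)
  meas <- vector("list", length(tubes))
  for (i in seq_along(tubes)) {
    tb <- tubes[[i]]
    sim <- simulate_dilution_tube(design, profile, mast_spec,
                                  tb$level, tb$level_index, tb$repeat_index,
                                  noise_cv)
    g <- quantify_mast_cells(sim$events, gates,
                             min_events = design$min_events)
    if (verbose) {
      message(sprintf(
        "[%s] level=%g%% repeat=%d: acquired=%d cells=%d viable=%d dp=%d mast_pct=%.4f",
        design$matrix, tb$level, tb$repeat_index, g$n_total, g$n_cells,
        g$n_viable, g$quadrant_counts[["pp"]], g$mast_pct))
    }
    meas[[i]] <- data.frame(
      matrix = design$matrix, nominal_fraction = tb$level,
      repeat_index = tb$repeat_index, mast_pct = g$mast_pct,
      n_cells = g$n_cells, n_viable = g$n_viable,
      realized_count = sim$truth$realized_count,
      min_events_met = g$min_events_met
    )
  }
  meas <- do.call(rbind, meas)
  summarize_validation(meas, design, pb_repeat = pb_repeat)
}

#' Assemble a validation report from tube-level measurements
#'
#' Computes every validation statistic from a measurement table (one row per
#' tube: `nominal_fraction`, `repeat_index`, `mast_pct`; blanks at nominal
#' 0). Separated from [run_validation()] so reports can also be built from
#' externally measured data.
#'
#' @param measurements Data.frame with at least `nominal_fraction`,
#'   `repeat_index`, `mast_pct`.
#' @param design The [experiment_design()] the measurements follow.
#' @param cv_threshold LLoQ CV threshold in percent (default 30).
#' @param pb_repeat Repeat used for accuracy points.
#' @return A list of class `validation_report` with `matrix`, `limits`
#'   (lob/llod/lloq and evidence), `precision` table, `overall_cv`, `pb`
#'   fit, `emu`, `uncertainty_examples`, `measurements`, `provenance`.
#' @export
summarize_validation <- function(measurements, design, cv_threshold = 30,
                                 pb_repeat = 1L) {
  blanks <- measurements$mast_pct[measurements$nominal_fraction == 0]
  levels_df <- measurements[measurements$nominal_fraction > 0, , drop = FALSE]

  limits <- list(lob = NA_real_, llod = NA_real_, lloq = NA_real_,
                 lloq_cv = NA_real_, blank_mean = NA_real_,
                 blank_sd = NA_real_)
  if (length(blanks) >= 2) {
    lb <- compute_lob(blanks)
    limits$lob <- lb$lob
    limits$blank_mean <- lb$blank_mean
    limits$blank_sd <- lb$blank_sd
    limits$llod <- compute_llod(lb$lob, lb$blank_sd)
  }

  precision <- NULL
  overall_cv <- NA_real_
  if (nrow(levels_df) > 0 &&
      all(table(levels_df$nominal_fraction) >= 2)) {
    precision <- build_precision_table(levels_df)
    overall_cv <- compute_overall_precision(precision$cv_a)
    if (!is.na(limits$llod)) {
      sel <- select_lloq(precision, limits$llod, cv_threshold = cv_threshold)
      limits$lloq <- sel$lloq
      limits$lloq_cv <- sel$lloq_cv
    }
  }

  pb <- NULL
  acc <- levels_df[levels_df$repeat_index == pb_repeat, , drop = FALSE]
  if (nrow(acc) >= 3) {
    pb <- pb_fit(acc$nominal_fraction, acc$mast_pct)
  }

  emu <- if (is.na(overall_cv)) NA_real_ else compute_emu(overall_cv)
  unc <- if (is.na(emu)) NULL else list(
    at_metastatic_cutoff = report_with_uncertainty(0.3, emu),
    at_hn3_cutoff = report_with_uncertainty(4, emu)
  )

  structure(list(
    matrix = design$matrix,
    limits = limits,
    precision = precision,
    overall_cv = overall_cv,
    pb = pb,
    emu = emu,
    uncertainty_examples = unc,
    measurements = measurements,
    provenance = list(
      rng_seed = design$rng_seed,
      design = unclass(design),
      n_tubes = nrow(measurements),
      schema_version = "1.0"
    )
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  fmt <- function(v, d = 3) ifelse(is.na(v), "not reached",
                                   format(round(v, d)))
  cat("<validation_report> matrix ", x$matrix, "\n",
      "  LOB:  ", fmt(x$limits$lob), "%\n",
      "  LLoD: ", fmt(x$limits$llod), "%\n",
      "  LLoQ: ", fmt(x$limits$lloq), "%",
      if (!is.na(x$limits$lloq))
        paste0(" (CV_A = ", fmt(x$limits$lloq_cv, 1), "%)"), "\n",
      "  overall precision: CV_A = ", fmt(x$overall_cv, 1), "%\n", sep = "")
  if (!is.null(x$pb)) print(x$pb)
  invisible(x)
}

#' Render a validation report to files
#'
#' Writes a machine-readable JSON report, a per-dilution precision table
#' (TSV) and a plain-text summary mirroring the JSON. An absent LLoQ is
#' rendered as `"not reached"` in the text summary and `null` in the JSON.
#'
#' @param report A `validation_report`.
#' @param dir Output directory (created if missing).
#' @return Character vector of the files written, invisibly.
#' @export
render_report <- function(report, dir) {
  stopifnot(inherits(report, "validation_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)

  js <- list(
    schema_version = report$provenance$schema_version,
    matrix = report$matrix,
    limits = report$limits,
    overall_cv = report$overall_cv,
    emu = report$emu,
    accuracy = if (is.null(report$pb)) NULL else list(
      slope = report$pb$slope, slope_ci = report$pb$slope_ci,
      intercept = report$pb$intercept,
      intercept_ci = report$pb$intercept_ci,
      bias = assess_bias(report$pb)
    ),
    precision = report$precision,
    measurements = report$measurements,
    provenance = report$provenance
  )
  json_path <- file.path(dir, "validation_report.json")
  jsonlite::write_json(js, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  files <- c(files, json_path)

  if (!is.null(report$precision)) {
    tsv_path <- file.path(dir, "precision_table.tsv")
    write.table(as.data.frame(report$precision), tsv_path, sep = "\t",
                row.names = FALSE, quote = FALSE)
    files <- c(files, tsv_path)
  }

  txt_path <- file.path(dir, "summary.txt")
  con <- file(txt_path, "w")
  sink(con)
  print(report)
  sink()
  close(con)
  files <- c(files, txt_path)
  invisible(files)
}

#' Plot a Passing-Bablok accuracy fit
#'
#' Scatter of measured against expected percentages with the identity line
#' (grey) and the fitted regression line; draws on the active graphics
#' device.
#'
#' @param pb A `pb_fit`.
#' @param x,y The data used in the fit.
#' @param ... Passed to [plot()].
#' @export
plot_pb_fit <- function(pb, x, y, ...) {
  stopifnot(inherits(pb, "pb_fit"))
  plot(x, y, xlab = "Expected mast cells (%)",
       ylab = "Measured mast cells (%)", ...)
  graphics::abline(0, 1, col = "grey")
  graphics::abline(pb$intercept, pb$slope, col = "red")
  graphics::legend("topleft", bty = "n", legend = sprintf(
    "slope %.3f (%.3f-%.3f)\nintercept %.3f (%.3f-%.3f)",
    pb$slope, pb$slope_ci[1], pb$slope_ci[2],
    pb$intercept, pb$intercept_ci[1], pb$intercept_ci[2]))
  invisible(pb)
}
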