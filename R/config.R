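# Key-value configuration files for experiment designs and gate settings.
#
# Format: one `key = value` per line, '#' comments, lists comma-separated,
# coordinate pairs separated by ';' (e.g. "100,5; 1500,5; 1500,2500").

parse_kv_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("malformed config line (expected 'key = value'): ", ln,
           call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    out[[key]] <- val
  }
  out
}

kv_numeric <- function(val, key) {
  x <- suppressWarnings(as.numeric(trimws(strsplit(val, ",")[[1]])))
  if (anyNA(x)) stop("non-numeric value for '", key, "': ", val, call. = FALSE)
  x
}

#' Default dilution scheme for a matrix
#'
#' Nominal spiked mast-cell fractions (percent of viable events) used in the
#' validation design: 10 down to 0.1% for peripheral blood (PB) and bone
#' marrow (BM), 50 down to 0.1% for lymph node (LN).
#'
#' @param matrix One of `"PB"`, `"BM"`, `"LN"`.
#' @return Numeric vector of nominal percentages, strictly decreasing.
#' @export
default_dilution_scheme <- function(matrix = c("PB", "BM", "LN")) {
  matrix <- match.arg(matrix)
  if (matrix == "LN") c(50, 25, 10, 5, 3, 1, 0.5, 0.3, 0.1)
  else c(10, 7, 5, 3, 2, 1, 0.5, 0.3, 0.1)
}

#' Default acquisition minimum for a matrix
#'
#' Minimum events to record in the morphological "cells" gate: 500,000 for
#' peripheral blood, 100,000 for bone marrow and lymph node.
#'
#' @inheritParams default_dilution_scheme
#' @return Integer event count.
#' @export
default_min_events <- function(matrix = c("PB", "BM", "LN")) {
  matrix <- match.arg(matrix)
  if (matrix == "PB") 500000L else 100000L
}

#' Construct a validation experiment design
#'
#' Describes one matrix's spike-in dilution study: the nominal fractions, the
#' number of repeats per dilution level, the number of blank (0%) negative
#' controls, the acquisition minimum and the master RNG seed from which every
#' tube's stream is derived.
#'
#' @param matrix `"PB"`, `"BM"` or `"LN"`.
#' @param nominal_fractions Strictly decreasing percentages in (0, 100];
#'   default [default_dilution_scheme()].
#' @param repeats_per_level Repeats per dilution level (>= 1).
#' @param n_blanks Number of blank negative controls (>= 0).
#' @param min_events Acquisition minimum in the morphology gate; default
#'   [default_min_events()].
#' @param rng_seed Integer master seed.
#' @return A list of class `experiment_design`.
#' @export
#' @examples
#' experiment_design("LN", repeats_per_level = 3, n_blanks = 10)
experiment_design <- function(matrix = c("PB", "BM", "LN"),
                              nominal_fractions = default_dilution_scheme(matrix),
                              repeats_per_level = 3L,
                              n_blanks = 10L,
                              min_events = default_min_events(matrix),
                              rng_seed = 1L) {
  matrix <- match.arg(matrix)
  f <- as.numeric(nominal_fractions)
  if (length(f) == 0 || any(f <= 0) || any(f > 100)) {
    stop("nominal_fractions must lie in (0, 100]; blanks are modelled via ",
         "n_blanks, not as a 0% level", call. = FALSE)
  }
  if (length(f) > 1 && any(diff(f) >= 0)) {
    stop("nominal_fractions must be strictly decreasing", call. = FALSE)
  }
  if (repeats_per_level < 1) stop("repeats_per_level must be >= 1",
                                  call. = FALSE)
  if (n_blanks < 0) stop("n_blanks must be >= 0", call. = FALSE)
  structure(list(
    matrix = matrix,
    nominal_fractions = f,
    repeats_per_level = as.integer(repeats_per_level),
    n_blanks = as.integer(n_blanks),
    min_events = as.integer(min_events),
    rng_seed = as.integer(rng_seed)
  ), class = "experiment_design")
}

#' Read an experiment design from a key-value config file
#'
#' Recognised keys: `matrix` (required), `nominal_fractions`,
#' `repeats_per_level`, `n_blanks`, `min_events`, `rng_seed`. Missing keys
#' fall back to the matrix defaults (e.g. `min_events` 500,000 for PB,
#' 100,000 for BM/LN).
#'
#' @param path Path to the config file.
#' @return An [experiment_design()].
#' @export
read_design <- function(path) {
  kv <- parse_kv_config(path)
  if (is.null(kv$matrix)) stop("design config must name 'matrix'",
                               call. = FALSE)
  matrix <- toupper(trimws(kv$matrix))
  if (!matrix %in% c("PB", "BM", "LN")) {
    stop("unknown matrix '", kv$matrix, "' (expected PB, BM or LN)",
         call. = FALSE)
  }
  args <- list(matrix = matrix)
  if (!is.null(kv$nominal_fractions)) {
    args$nominal_fractions <- kv_numeric(kv$nominal_fractions,
                                         "nominal_fractions")
  }
  for (key in c("repeats_per_level", "n_blanks", "min_events", "rng_seed")) {
    if (!is.null(kv[[key]])) args[[key]] <- kv_numeric(kv[[key]], key)
  }
  do.call(experiment_design, args)
}

#' Read a gate configuration from a key-value config file
#'
#' Recognised keys: `morph_polygon` (semicolon-separated `fsc,ssc` vertex
#' pairs), `viability_max_fl3`, `ige_threshold`, `cd117_threshold`. Missing
#' keys fall back to [default_gate_config()].
#'
#' @param path Path to the config file.
#' @return A [gate_config()].
#' @export
read_gate_config <- function(path) {
  kv <- parse_kv_config(path)
  def <- default_gate_config()
  poly <- def$morph_polygon
  if (!is.null(kv$morph_polygon)) {
    pairs <- strsplit(kv$morph_polygon, ";")[[1]]
    xy <- t(vapply(pairs, function(p) kv_numeric(p, "morph_polygon"),
                   numeric(2)))
    poly <- cbind(fsc = xy[, 1], ssc = xy[, 2])
  }
  num_or <- function(key, default) {
    if (is.null(kv[[key]])) default else kv_numeric(kv[[key]], key)
  }
  gate_config(
    morph_polygon = poly,
    viability_max_fl3 = num_or("viability_max_fl3", def$viability_max_fl3),
    ige_threshold = num_or("ige_threshold", def$ige_threshold),
    cd117_threshold = num_or("cd117_threshold", def$cd117_threshold)
  )
}
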