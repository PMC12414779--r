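# EventTable: listmode cytometry events as a validated data.frame.

#' Canonical channel names of an event table
#' @return Character vector of the five channel column names.
#' @export
event_channels <- function() {
  c("fsc", "ssc", "fl1_ige", "fl2_cd117", "fl3_7aad")
}

#' Recognised ground-truth population labels
#' @return Character vector of valid `label` values.
#' @export
population_labels <- function() {
  c("lymphocyte", "monocyte", "granulocyte", "precursor",
    "debris", "dead", "mast_cell", "other")
}

#' Construct a listmode event table
#'
#' An `event_table` holds per-event channel intensities for the five channels
#' used by the mast-cell panel: forward scatter (`fsc`), side scatter (`ssc`),
#' IgE-FITC (`fl1_ige`), CD117-PE (`fl2_cd117`) and the 7-AAD viability dye
#' (`fl3_7aad`). All intensities are linear, finite and non-negative. An
#' optional `label` column carries the ground-truth population of each event
#' (synthetic data only).
#'
#' @param x A data.frame with the five channel columns (and optionally
#'   `label`), or a list/environment coercible to one.
#' @return A data.frame of class `event_table`.
#' @export
#' @examples
#' ev <- event_table(data.frame(
#'   fsc = c(100, 200), ssc = c(50, 60), fl1_ige = c(1, 2),
#'   fl2_cd117 = c(1, 2), fl3_7aad = c(3, 4)
#' ))
#' n_events(ev)
event_table <- function(x) {
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  validate_event_table(df)
  keep <- c(event_channels(), if ("label" %in% names(df)) "label")
  df <- df[, keep, drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("event_table", "data.frame")
  df
}

validate_event_table <- function(df) {
  miss <- setdiff(event_channels(), names(df))
  if (length(miss) > 0) {
    stop("event table is missing channel column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (ch in event_channels()) {
    v <- df[[ch]]
    if (!is.numeric(v)) {
      stop("channel '", ch, "' is not numeric", call. = FALSE)
    }
    if (anyNA(v) || any(!is.finite(v))) {
      stop("channel '", ch, "' contains non-finite values", call. = FALSE)
    }
    if (any(v < 0)) {
      stop("channel '", ch, "' contains negative values", call. = FALSE)
    }
  }
  if ("label" %in% names(df)) {
    lab <- as.character(df$label)
    if (anyNA(lab)) stop("labels, when present, must cover every event",
                         call. = FALSE)
    bad <- setdiff(unique(lab), population_labels())
    if (length(bad) > 0) {
      stop("unknown population label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(df)
}

#' @export
print.event_table <- function(x, ...) {
  cat("<event_table> ", nrow(x), " events, ",
      if ("label" %in% names(x)) "labelled" else "unlabelled", "\n", sep = "")
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5) cat("... (", nrow(x) - 5L, " more events)\n", sep = "")
  invisible(x)
}

#' Number of events in an event table
#' @param events An `event_table`.
#' @return Integer event count.
#' @export
n_events <- function(events) nrow(events)

#' Read listmode events from a CSV or FCS file
#'
#' CSV files must carry a header naming the five canonical channels (see
#' [event_channels()]); a trailing `label` column is honoured. FCS files are
#' read through the package's FCS 3.x list-mode reader, with parameter short
#' names mapped onto channels via `channel_map`.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"csv"` or `"fcs"`.
#' @param channel_map Named character vector mapping FCS `$PnN` short names to
#'   canonical channel names; default [default_channel_map()].
#' @return An [event_table()] preserving event order.
#' @export
read_events <- function(path, format = c("auto", "csv", "fcs"),
                        channel_map = default_channel_map()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  }
  if (format == "fcs") return(read_fcs(path, channel_map = channel_map))
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(event_channels(), names(df))
  if (length(miss) > 0) {
    stop("CSV is missing channel column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (ch in event_channels()) {
    v <- df[[ch]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      if (anyNA(num)) {
        stop("non-numeric value in channel '", ch, "' at data row ",
             which(is.na(num))[1], call. = FALSE)
      }
      df[[ch]] <- num
    }
  }
  event_table(df)
}

#' Write listmode events to a CSV or FCS file
#'
#' CSV output keeps a `label` column (if present) as the last column; FCS
#' output drops labels with a warning since FCS stores numeric parameters
#' only.
#'
#' @param events An [event_table()].
#' @param path Output path.
#' @param format `"auto"` (by extension), `"csv"` or `"fcs"`.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, format = c("auto", "csv", "fcs")) {
  format <- match.arg(format)
  validate_event_table(events)
  if (format == "auto") {
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  }
  if (format == "fcs") {
    if ("label" %in% names(events)) {
      warning("FCS stores numeric parameters only; dropping 'label' column")
    }
    return(write_fcs(events, path))
  }
  cols <- c(event_channels(), if ("label" %in% names(events)) "label")
  ok <- tryCatch({
    write.csv(as.data.frame(events)[, cols, drop = FALSE], path,
              row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("could not write '", path, "': ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}
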