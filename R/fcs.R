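# Minimal FCS 3.1 list-mode I/O (float32, little-endian, linear channels).
#
# Only the dialect this package writes is guaranteed to round-trip: HEADER +
# primary TEXT + DATA, $DATATYPE/F, $MODE/L. Vendor-specific keywords are
# ignored on read; spillover/compensation is out of scope.

#' Default mapping from FCS parameter short names to canonical channels
#'
#' Matches the panel's fluorochromes: FL1 carries IgE-FITC, FL2 CD117-PE and
#' FL3 the 7-AAD viability dye.
#'
#' @return Named character vector: names are `$PnN` short names, values are
#'   canonical channel names.
#' @export
default_channel_map <- function() {
  c("FSC-H" = "fsc", "SSC-H" = "ssc", "FL1-H" = "fl1_ige",
    "FL2-H" = "fl2_cd117", "FL3-H" = "fl3_7aad")
}

fcs_delim <- "/"

write_fcs <- function(events, path) {
  m <- as.matrix(as.data.frame(events)[, event_channels(), drop = FALSE])
  storage.mode(m) <- "double"
  n <- nrow(m)
  par <- ncol(m)
  cmap <- default_channel_map()
  short_names <- names(cmap)[match(event_channels(), cmap)]

  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BEGINDATA" = sprintf("%012d", 0), "$ENDDATA" = sprintf("%012d", 0),
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0", "$PAR" = as.character(par), "$TOT" = as.character(n)
  )
  for (i in seq_len(par)) {
    kw[[sprintf("$P%dB", i)]] <- "32"
    kw[[sprintf("$P%dE", i)]] <- "0,0"
    kw[[sprintf("$P%dN", i)]] <- short_names[i]
    kw[[sprintf("$P%dR", i)]] <- as.character(max(1024, ceiling(max(m[, i], 1))))
  }
  text_of <- function(kw) {
    paste0(fcs_delim,
           paste0(names(kw), fcs_delim, unname(kw), fcs_delim, collapse = ""))
  }
  txt <- text_of(kw)
  text_begin <- 58L
  text_end <- text_begin + nchar(txt) - 1L
  data_begin <- text_end + 1L
  data_end <- data_begin + 4L * par * n - 1L
  if (n == 0) { data_begin <- 0L; data_end <- 0L }
  # zero-padded widths keep the TEXT segment length fixed after substitution
  kw[["$BEGINDATA"]] <- sprintf("%012d", data_begin)
  kw[["$ENDDATA"]] <- sprintf("%012d", data_end)
  txt <- text_of(kw)

  off <- function(x) {
    if (x <= 99999999) sprintf("%8d", x) else sprintf("%8d", 0L)
  }
  header <- paste0("FCS3.1    ", off(text_begin), off(text_end),
                   off(data_begin), off(data_end), off(0L), off(0L))
  stopifnot(nchar(header) == 58L)

  con <- tryCatch(file(path, "wb"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e),
         call. = FALSE)
  })
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(txt, con, eos = NULL)
  if (n > 0) {
    # row-major event-by-event order, float32
    writeBin(as.vector(t(m)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

parse_fcs_text <- function(raw_txt) {
  delim <- substr(raw_txt, 1L, 1L)
  body <- substr(raw_txt, 2L, nchar(raw_txt))
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- parts[seq(1, length(parts), by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  stats::setNames(as.list(vals), toupper(trimws(keys)))
}

read_fcs <- function(path, channel_map = default_channel_map()) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  if (!grepl("^FCS3", header)) {
    stop("not an FCS 3.x file: ", path, call. = FALSE)
  }
  offs <- suppressWarnings(as.integer(substring(
    header, 10 + 8 * (0:5) + 1, 10 + 8 * (1:6))))
  text_begin <- offs[1]; text_end <- offs[2]
  seek(con, text_begin)
  txt <- readChar(con, text_end - text_begin + 1L, useBytes = TRUE)
  kw <- parse_fcs_text(txt)

  need <- function(k) {
    if (is.null(kw[[k]])) stop("FCS TEXT lacks required keyword ", k,
                               call. = FALSE)
    kw[[k]]
  }
  if (toupper(need("$DATATYPE")) != "F") {
    stop("unsupported $DATATYPE '", kw[["$DATATYPE"]],
         "' (only F is supported)", call. = FALSE)
  }
  if (toupper(need("$MODE")) != "L") {
    stop("unsupported $MODE (only list mode L)", call. = FALSE)
  }
  endian <- if (grepl("^4", need("$BYTEORD"))) "big" else "little"
  par <- as.integer(need("$PAR"))
  tot <- as.integer(need("$TOT"))
  data_begin <- as.integer(need("$BEGINDATA"))
  data_end <- as.integer(need("$ENDDATA"))
  if (data_begin == 0 && offs[3] > 0) { data_begin <- offs[3]; data_end <- offs[4] }

  vals <- if (tot > 0) {
    seek(con, data_begin)
    readBin(con, what = "numeric", n = par * tot, size = 4L, endian = endian)
  } else numeric(0)
  if (length(vals) != par * tot) {
    stop("FCS data segment truncated: expected ", par * tot, " values, got ",
         length(vals), call. = FALSE)
  }
  m <- matrix(vals, ncol = par, byrow = TRUE)
  short_names <- vapply(seq_len(par),
                        function(i) kw[[sprintf("$P%dN", i)]] %||% "",
                        character(1))
  canon <- unname(channel_map[short_names])
  for (ch in event_channels()) {
    if (!ch %in% canon) {
      stop("FCS parameters do not map onto channel '", ch,
           "'; adjust channel_map (found: ",
           paste(short_names, collapse = ", "), ")", call. = FALSE)
    }
  }
  df <- as.data.frame(m[, match(event_channels(), canon), drop = FALSE])
  names(df) <- event_channels()
  # float32 storage can introduce tiny negative rounding of zeros
  df[df < 0 & df > -1e-6] <- 0
  event_table(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
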