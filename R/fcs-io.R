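#' Read a minimal FCS 3.0/3.1 list-mode file
#'
#' Decodes the HEADER and primary TEXT segment of an FCS 3.0 or 3.1 file and
#' returns the DATA segment as an [event_table()]. Only list mode
#' (`$MODE = L`) with `$DATATYPE` `I` (unsigned integer, uniform 8/16/32 bit)
#' or `F` (32-bit float) is supported, in either `$BYTEORD` byte order; this
#' covers the raw, uncompensated exports of benchtop instruments. A
#' `$SPILLOVER` keyword, if present, is ignored with a warning — all
#' statistics in this package are defined on raw channel values.
#'
#' Acquisition metadata written by [write_fcs()] (non-standard `FSEG*`
#' keywords) is restored on re-read; files from other software get `NA`
#' ("unknown") metadata.
#'
#' @param path Path to an FCS file.
#' @return An [event_table()] with one column per `$PnN` parameter.
#' @seealso [write_fcs()], [read_listmode_csv()]
#' @export
read_fcs <- function(path) {
  if (!file.exists(path)) stop_flowseg("io", paste0("no such file: ", path))
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 58) stop_flowseg("corrupt_file", "file shorter than an FCS header")
  version <- rawToChar(raw[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stop_flowseg("unsupported_format",
      paste0("unsupported FCS version '", version, "' (need FCS3.0 or FCS3.1)"))
  }
  off <- function(i, j) {
    s <- trimws(rawToChar(raw[i:j]))
    if (s == "") 0 else suppressWarnings(as.numeric(s))
  }
  text_begin <- off(11, 18); text_end <- off(19, 26)
  data_begin <- off(27, 34); data_end <- off(35, 42)
  if (is.na(text_begin) || is.na(text_end) || text_end <= text_begin ||
      text_end + 1 > length(raw)) {
    stop_flowseg("corrupt_file", "invalid TEXT segment offsets in HEADER")
  }

  txt <- rawToChar(raw[(text_begin + 1):(text_end + 1)])
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 != 0) parts <- parts[-length(parts)]
  kw <- setNames(as.list(parts[seq(2, length(parts), 2)]),
                 toupper(parts[seq(1, length(parts), 2)]))

  need <- function(key, err = "corrupt_file") {
    if (is.null(kw[[key]])) {
      stop_flowseg(err, paste0("required keyword ", key, " missing from TEXT segment"))
    }
    kw[[key]]
  }
  mode <- need("$MODE")
  if (mode != "L") {
    stop_flowseg("unsupported_format",
      paste0("unsupported $MODE '", mode, "': only list mode (L) is supported"))
  }
  dtype <- need("$DATATYPE")
  if (!dtype %in% c("I", "F")) {
    stop_flowseg("unsupported_format",
      paste0("unsupported $DATATYPE '", dtype, "': only I and F are supported"))
  }
  byteord <- need("$BYTEORD")
  endian <- switch(byteord, "1,2,3,4" = "little", "4,3,2,1" = "big",
    stop_flowseg("unsupported_format",
      paste0("unsupported $BYTEORD '", byteord, "'")))
  tot <- as.integer(need("$TOT"))
  par <- as.integer(need("$PAR"))
  if (is.na(tot) || is.na(par) || tot < 0 || par < 1) {
    stop_flowseg("corrupt_file", "invalid $TOT/$PAR values")
  }

  bits <- vapply(seq_len(par), function(i) {
    as.integer(need(paste0("$P", i, "B")))
  }, integer(1))
  if (length(unique(bits)) != 1) {
    stop_flowseg("unsupported_format", "non-uniform $PnB bit widths are not supported")
  }
  nbit <- bits[[1]]
  if (dtype == "F" && nbit != 32) {
    stop_flowseg("unsupported_format", "$DATATYPE F requires $PnB = 32")
  }
  if (dtype == "I" && !nbit %in% c(8L, 16L, 32L)) {
    stop_flowseg("unsupported_format", "$DATATYPE I supports $PnB of 8, 16 or 32 only")
  }
  ch <- vapply(seq_len(par), function(i) {
    nm <- kw[[paste0("$P", i, "N")]]
    if (is.null(nm) || nm == "") paste0("P", i) else nm
  }, character(1))

  if (!is.null(kw[["$SPILLOVER"]])) {
    warn("$SPILLOVER present but ignored: statistics are computed on raw channel values")
  }

  if (data_begin == 0 && !is.null(kw[["$BEGINDATA"]])) {
    data_begin <- as.numeric(kw[["$BEGINDATA"]])
    data_end <- as.numeric(kw[["$ENDDATA"]])
  }
  expected <- tot * par * (nbit / 8)
  if (tot == 0) {
    mat <- matrix(numeric(0), nrow = 0, ncol = par)
  } else {
    if (data_begin <= 0 || data_end + 1 > length(raw) ||
        (data_end - data_begin + 1) != expected) {
      stop_flowseg("corrupt_file",
        "$TOT inconsistent with the DATA segment length")
    }
    seg <- raw[(data_begin + 1):(data_end + 1)]
    vals <- if (dtype == "F") {
      readBin(seg, "double", n = tot * par, size = 4, endian = endian)
    } else {
      readBin(seg, "integer", n = tot * par, size = nbit / 8,
              signed = nbit >= 32, endian = endian)
    }
    mat <- matrix(as.numeric(vals), nrow = tot, ncol = par, byrow = TRUE)
  }
  colnames(mat) <- ch

  grab <- function(key) {
    v <- kw[[key]]
    if (is.null(v)) NA_real_ else suppressWarnings(as.numeric(v))
  }
  cap <- grab("FSEGCAP")
  event_table(as.data.frame(mat, check.names = FALSE),
    time_h = grab("FSEGTIMEH"),
    duration_s = grab("FSEGDURS"),
    flow_rate_ul_min = grab("FSEGFLOW"),
    event_cap = if (is.na(cap)) NA_integer_ else as.integer(cap),
    truncated = identical(kw[["FSEGTRUNC"]], "1"))
}

#' Write an event table as a minimal FCS 3.1 file
#'
#' Emits list mode (`$MODE = L`), `$DATATYPE = F` (32-bit little-endian
#' floats), one `$PnN` per channel. Acquisition metadata is stored in
#' non-standard `FSEG*` keywords so that [read_fcs()] round-trips it; other
#' FCS software simply ignores them.
#'
#' @param table An [event_table()]; channel names must be ASCII and values
#'   representable as 32-bit floats.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(table, path) {
  if (ncol(table) == 0) {
    stop_flowseg("invalid_table", "cannot write an event table with zero channels")
  }
  ch <- names(table)
  if (any(grepl("[^\x20-\x7E]", ch))) {
    stop_flowseg("invalid_table", "channel names must be printable ASCII")
  }
  n <- nrow(table)
  p <- length(ch)
  m <- acquisition_meta(table)

  rng <- vapply(seq_len(p), function(i) {
    v <- table[[i]]
    max(262144, if (length(v)) 2^ceiling(log2(max(v) + 1)) else 0)
  }, numeric(1))

  kv <- c(
    "$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
    "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
    "$BEGINDATA", "%BD%", "$ENDDATA", "%ED%",
    "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
    "$NEXTDATA", "0", "$TOT", as.character(n), "$PAR", as.character(p))
  for (i in seq_len(p)) {
    kv <- c(kv,
      paste0("$P", i, "N"), ch[[i]],
      paste0("$P", i, "B"), "32",
      paste0("$P", i, "E"), "0,0",
      paste0("$P", i, "R"), format(rng[[i]], scientific = FALSE))
  }
  addmeta <- function(kv, key, val) {
    if (length(val) == 1 && !is.na(val)) c(kv, key, format(val, scientific = FALSE)) else kv
  }
  kv <- addmeta(kv, "FSEGTIMEH", m$time_h)
  kv <- addmeta(kv, "FSEGDURS", m$duration_s)
  kv <- addmeta(kv, "FSEGFLOW", m$flow_rate_ul_min)
  kv <- addmeta(kv, "FSEGCAP", m$event_cap)
  kv <- c(kv, "FSEGTRUNC", if (isTRUE(m$truncated)) "1" else "0")

  text_tpl <- paste0("/", paste(kv, collapse = "/"), "/")
  # offsets inside TEXT are written fixed-width so the segment length is
  # independent of their value
  text_len <- nchar(sub("%BD%", sprintf("%8d", 0),
                        sub("%ED%", sprintf("%8d", 0), text_tpl), fixed = TRUE))
  data_begin <- 58 + text_len
  nbytes <- 4 * n * p
  bd <- if (nbytes > 0) data_begin else 0
  ed <- if (nbytes > 0) data_begin + nbytes - 1 else 0
  text <- sub("%BD%", sprintf("%8d", bd),
              sub("%ED%", sprintf("%8d", ed), text_tpl, fixed = TRUE), fixed = TRUE)
  stopifnot(nchar(text) == text_len)

  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    58, 58 + text_len - 1, bd, ed, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(header, text)), con)
  if (n > 0) {
    vals <- as.numeric(t(as.matrix(table)))
    writeBin(vals, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read an instrument CSV listmode export
#'
#' Parses the comma-separated listmode dialect produced by benchtop cytometer
#' software: a mandatory header row of channel names followed by one numeric
#' row per event (`.` decimal separator, UTF-8). Acquisition metadata is not
#' part of this format, so all metadata fields of the result are `NA`
#' (unknown). Values are taken to be linear-scale raw channel intensities,
#' not log-transformed; all downstream statistics assume this.
#'
#' @param path Path to the CSV file.
#' @return An [event_table()].
#' @export
read_listmode_csv <- function(path) {
  if (!file.exists(path)) stop_flowseg("io", paste0("no such file: ", path))
  hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  hdr <- trimws(hdr)
  if (anyDuplicated(hdr)) {
    stop_flowseg("format", paste0(
      "duplicate channel name(s) in header: ",
      paste(unique(hdr[duplicated(hdr)]), collapse = ", ")))
  }
  df <- read.csv(path, check.names = FALSE, colClasses = "character",
                 strip.white = TRUE)
  out <- vector("list", length(hdr))
  names(out) <- hdr
  for (j in seq_along(hdr)) {
    v <- df[[j]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & v != "NA")
    if (length(bad)) {
      stop_flowseg("parse", sprintf(
        "non-numeric value '%s' at row %d, column '%s'",
        v[bad[1]], bad[1], hdr[j]))
    }
    out[[j]] <- num
  }
  event_table(as.data.frame(out, check.names = FALSE))
}

#' Write an event table as a CSV listmode export
#'
#' Symmetric writer for [read_listmode_csv()]: header row of channel names,
#' one row per event, comma separated, `.` decimal. Acquisition metadata is
#' not representable in this format and is dropped.
#'
#' @inheritParams write_fcs
#' @return `path`, invisibly.
#' @export
write_listmode_csv <- function(table, path) {
  if (ncol(table) == 0) {
    stop_flowseg("invalid_table", "cannot write an event table with zero channels")
  }
  write.table(as.data.frame(table), path, sep = ",", dec = ".",
              row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
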