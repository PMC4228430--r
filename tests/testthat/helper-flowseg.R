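# shared fixture builders (all fixtures are generated in code)

# a small table with FSC guaranteed above the default acquisition threshold
make_table <- function(n = 10, seed = 1, channels = c("FSC", "SSC", "FL1", "FL3")) {
  withr::with_seed(seed, {
    df <- as.data.frame(setNames(
      lapply(channels, function(ch) {
        if (ch == "FSC") stats::runif(n, 1e5, 4e5) else stats::runif(n, 1, 5e4)
      }), channels))
    event_table(df)
  })
}

# independent type-7 quantile (linear interpolation of order statistics),
# used as the oracle for calibration quantiles
brute_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
}

# independent median via direct sort (mid-average of central order statistics)
brute_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

# hand-assembled minimal FCS file with $DATATYPE I, used to exercise the
# integer decoding path independently of write_fcs
make_fcs_int <- function(path, values_by_event, channels, bits = 16,
                         byteord = c("little", "big"), drop_keyword = NULL) {
  byteord <- match.arg(byteord)
  n <- nrow(values_by_event)
  p <- ncol(values_by_event)
  kv <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BEGINDATA", "%BD%", "$ENDDATA", "%ED%",
          "$BYTEORD", if (byteord == "little") "1,2,3,4" else "4,3,2,1",
          "$DATATYPE", "I", "$MODE", "L", "$NEXTDATA", "0",
          "$TOT", as.character(n), "$PAR", as.character(p))
  for (i in seq_len(p)) {
    kv <- c(kv, paste0("$P", i, "N"), channels[[i]],
            paste0("$P", i, "B"), as.character(bits),
            paste0("$P", i, "E"), "0,0",
            paste0("$P", i, "R"), as.character(2^bits))
  }
  if (!is.null(drop_keyword)) {
    j <- which(kv == drop_keyword)
    kv <- kv[-c(j, j + 1)]
  }
  tpl <- paste0("/", paste(kv, collapse = "/"), "/")
  text_len <- nchar(gsub("%BD%|%ED%", sprintf("%8d", 0), tpl))
  bd <- 58 + text_len
  ed <- bd + n * p * bits / 8 - 1
  text <- sub("%BD%", sprintf("%8d", bd),
              sub("%ED%", sprintf("%8d", ed), tpl, fixed = TRUE), fixed = TRUE)
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d", 58, 58 + text_len - 1, bd, ed, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(header, text)), con)
  writeBin(as.integer(t(values_by_event)), con, size = bits / 8, endian = byteord)
  path
}
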