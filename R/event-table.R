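#' List-mode cytometry event tables
#'
#' An `event_table` is a tibble with one row per recorded event and one
#' numeric column per detector channel (typically `FSC`, `SSC`, `FL1` for
#' green/GFP fluorescence and `FL3` for red/propidium-iodide fluorescence,
#' all linear arbitrary units), plus acquisition metadata carried as
#' attributes:
#'
#' * `time_h` — sample timestamp, hours from culture start
#' * `duration_s` — acquisition duration in seconds
#' * `flow_rate_ul_min` — cytometer flow rate in microlitres per minute
#' * `event_cap` — the configured maximum number of events per acquisition
#' * `truncated` — `TRUE` if recording stopped because the cap was reached
#'
#' Metadata that is unknown (e.g. when reading a bare CSV export) is stored
#' as `NA`, never silently as 0. All channel values must be finite and
#' non-negative; when `truncated` is `TRUE` the number of rows must equal
#' `event_cap`.
#'
#' @param events A data frame of numeric, non-negative channel values
#'   (one column per channel, one row per event).
#' @param time_h,duration_s,flow_rate_ul_min,event_cap Acquisition metadata
#'   (see above); `NA` marks unknown.
#' @param truncated Logical; did the event cap stop the acquisition?
#'
#' @return A tibble of class `event_table`.
#' @examples
#' tbl <- event_table(data.frame(FSC = 1e5, FL1 = 20, FL3 = 150))
#' n_events(tbl)
#' @export
event_table <- function(events, time_h = NA_real_, duration_s = NA_real_,
                        flow_rate_ul_min = NA_real_, event_cap = NA_integer_,
                        truncated = FALSE) {
  events <- as_tibble(as.data.frame(events, check.names = FALSE))
  nm <- names(events)
  if (anyDuplicated(nm)) {
    stop_flowseg("format", paste0(
      "duplicate channel name(s): ",
      paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  for (ch in nm) {
    v <- events[[ch]]
    if (!is.numeric(v)) {
      stop_flowseg("format", paste0("channel '", ch, "' is not numeric"))
    }
    if (nrow(events) > 0 && (!all(is.finite(v)) || any(v < 0))) {
      stop_flowseg("format", paste0(
        "channel '", ch, "' contains non-finite or negative values"))
    }
  }
  if (isTRUE(truncated) && !is.na(event_cap) && nrow(events) != event_cap) {
    stop_flowseg("format",
      "truncated = TRUE but n_events does not equal the event cap")
  }
  structure(events,
    class = c("event_table", class(tibble())),
    acquisition_meta = list(
      time_h = as.numeric(time_h),
      duration_s = as.numeric(duration_s),
      flow_rate_ul_min = as.numeric(flow_rate_ul_min),
      event_cap = if (is.na(event_cap)) NA_integer_ else as.integer(event_cap),
      truncated = isTRUE(truncated)))
}

#' Number of events in an event table
#' @param table An [event_table()].
#' @return Integer event count.
#' @export
n_events <- function(table) nrow(table)

#' Acquisition metadata of an event table
#' @param table An [event_table()].
#' @return Named list with `time_h`, `duration_s`, `flow_rate_ul_min`,
#'   `event_cap`, `truncated` (`NA` = unknown).
#' @export
acquisition_meta <- function(table) {
  m <- attr(table, "acquisition_meta")
  if (is.null(m)) {
    m <- list(time_h = NA_real_, duration_s = NA_real_,
              flow_rate_ul_min = NA_real_, event_cap = NA_integer_,
              truncated = FALSE)
  }
  m
}

# rebuild an event_table around a plain data frame, copying metadata from a
# template (used by filters that must carry acquisition_meta through)
rewrap_events <- function(events, template) {
  m <- acquisition_meta(template)
  out <- as_tibble(as.data.frame(events, check.names = FALSE))
  structure(out,
    class = c("event_table", class(tibble())),
    acquisition_meta = m)
}

#' @export
print.event_table <- function(x, ...) {
  m <- acquisition_meta(x)
  cat(sprintf("<event_table: %d events x %d channels>\n", nrow(x), ncol(x)))
  cat(sprintf("  t = %s h, duration = %s s, truncated = %s\n",
              format(m$time_h), format(m$duration_s), m$truncated))
  NextMethod()
}
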