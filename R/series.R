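#' Build a time series of segregation summaries
#'
#' Orders a collection of [summarize_sample()] results by sample time into a
#' `segregation_series`, the per-reactor analysis deliverable: from it the
#' trajectories of any statistic — gate fractions, degree of segregation,
#' per-channel or per-gate MMR — can be extracted as tidy tibbles.
#'
#' @param summaries A list of `sample_summary` objects with unique
#'   timestamps (an empty list yields an empty series).
#' @param reactor_id Optional reactor identifier.
#' @return A `segregation_series` object.
#' @export
build_series <- function(summaries, reactor_id = NA_character_) {
  if (inherits(summaries, "sample_summary")) summaries <- list(summaries)
  stopifnot(all(vapply(summaries, inherits, logical(1), "sample_summary")))
  times <- vapply(summaries, `[[`, numeric(1), "time")
  if (anyDuplicated(times)) {
    stop_flowseg("duplicate_time", "sample timestamps must be unique")
  }
  summaries <- summaries[order(times)]
  channels <- if (length(summaries)) summaries[[1]]$channels else character(0)
  structure(list(summaries = summaries, reactor_id = reactor_id,
                 channels = channels),
            class = "segregation_series")
}

#' @export
length.segregation_series <- function(x) length(x$summaries)

#' Sample times of a segregation series
#' @param series A `segregation_series`.
#' @return Numeric vector of sample times (h), increasing.
#' @export
series_times <- function(series) {
  vapply(series$summaries, `[[`, numeric(1), "time")
}

#' @export
print.segregation_series <- function(x, ...) {
  t <- series_times(x)
  cat(sprintf("<segregation_series: %d samples%s%s>\n", length(x),
              if (length(t)) sprintf(", t = %g..%g h", min(t), max(t)) else "",
              if (is.na(x$reactor_id)) "" else paste0(", reactor ", x$reactor_id)))
  invisible(x)
}

#' Tidy a segregation series
#'
#' Long format: one row per sample x gate x channel, with columns `time`,
#' `gate`, `channel`, `n`, `mean`, `median`, `mmr`, `low_count`, plus the
#' per-sample `degree_of_segregation` and gate `fraction` repeated on the
#' matching rows.
#'
#' @param x A `segregation_series`.
#' @param ... Unused.
#' @method tidy segregation_series
#' @export
tidy.segregation_series <- function(x, ...) {
  if (length(x) == 0) {
    return(tibble(time = numeric(0), gate = character(0), channel = character(0),
                  n = integer(0), mean = numeric(0), median = numeric(0),
                  mmr = numeric(0), low_count = logical(0),
                  fraction = numeric(0), degree_of_segregation = numeric(0)))
  }
  purrr::map_dfr(x$summaries, function(s) {
    out <- dplyr::mutate(s$stats, time = s$time, .before = 1)
    out$fraction <- s$fractions$fraction[match(out$gate, s$fractions$gate)]
    out$degree_of_segregation <- s$degree_of_segregation
    out
  })
}

#' One-row-per-sample view of a segregation series
#'
#' Wide format suitable for CSV export: one row per sample, columns named
#' `statistic_channel_gate` (e.g. `mmr_FL3_overall`, `mean_FL1_R2`), plus
#' `frac_<gate>` and `degree_of_segregation`.
#'
#' @param x A `segregation_series`.
#' @param ... Unused.
#' @method glance segregation_series
#' @export
glance.segregation_series <- function(x, ...) {
  if (length(x) == 0) return(tibble(time = numeric(0)))
  long <- tidy(x)
  stats <- tidyr::pivot_longer(long, c("mean", "median", "mmr"),
                               names_to = "stat", values_to = "value")
  stats$key <- paste(stats$stat, stats$channel, stats$gate, sep = "_")
  wide <- tidyr::pivot_wider(
    stats[, c("time", "key", "value")], names_from = "key", values_from = "value")
  fr <- dplyr::distinct(long[!is.na(long$fraction),
                             c("time", "gate", "fraction", "degree_of_segregation")])
  fr$key <- paste0("frac_", fr$gate)
  frw <- tidyr::pivot_wider(fr[, c("time", "key", "fraction")],
                            names_from = "key", values_from = "fraction")
  deg <- dplyr::distinct(long[, c("time", "degree_of_segregation")])
  out <- dplyr::left_join(dplyr::left_join(deg, frw, by = "time"), wide, by = "time")
  dplyr::arrange(out, .data$time)
}

#' Write a segregation series to CSV
#'
#' Writes the [glance()][glance.segregation_series] one-row-per-sample table.
#' @param series A `segregation_series`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  write.table(as.data.frame(glance(series)), path, sep = ",",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot segregation statistics over time
#'
#' Draws the on-line segregation indicators of a series as stacked panels:
#' gate fractions, degree of segregation, and the overall MMR of the chosen
#' channel.
#'
#' @param object A `segregation_series`.
#' @param channel Channel whose overall MMR to show (default `"FL3"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot segregation_series
#' @export
autoplot.segregation_series <- function(object, channel = "FL3", ...) {
  g <- glance(object)
  panels <- list()
  fr_cols <- grep("^frac_", names(g), value = TRUE)
  long <- tidyr::pivot_longer(g[, c("time", fr_cols)], -"time",
                              names_to = "gate", values_to = "value")
  long$gate <- sub("^frac_", "", long$gate)
  long$panel <- "gate fraction"
  d <- tibble(time = g$time, gate = NA_character_,
              value = g$degree_of_segregation, panel = "degree of segregation")
  mcol <- paste0("mmr_", channel, "_overall")
  m <- tibble(time = g$time, gate = NA_character_,
              value = g[[mcol]], panel = paste0("MMR (", channel, ")"))
  df <- dplyr::bind_rows(long, d, m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$gate)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 0.8, na.rm = TRUE) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = NULL, colour = "gate") +
    ggplot2::theme_minimal()
}

#' Dotplot of a cytometry sample
#'
#' FL3/FL1 dotplot on log10 axes with optional gate rectangles — the visual
#' counterpart of per-sample gating.
#'
#' @param object An [event_table()].
#' @param gateset Optional [gate_set()] whose FL3/FL1 bounds are drawn.
#' @param x_channel,y_channel Channels to plot (defaults FL3, FL1).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot event_table
#' @export
autoplot.event_table <- function(object, gateset = NULL,
                                 x_channel = "FL3", y_channel = "FL1", ...) {
  df <- tibble(x = pmax(object[[x_channel]], 1),
               y = pmax(object[[y_channel]], 1))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.4) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = x_channel, y = y_channel) +
    ggplot2::theme_minimal()
  if (!is.null(gateset)) {
    rects <- purrr::map_dfr(gateset$gates, function(g) {
      gx <- g$bounds[[x_channel]]
      gy <- g$bounds[[y_channel]]
      tibble(name = g$name,
             xmin = if (is.null(gx)) 1 else max(gx[["low"]], 1),
             xmax = if (is.null(gx)) Inf else gx[["high"]],
             ymin = if (is.null(gy)) 1 else max(gy[["low"]], 1),
             ymax = if (is.null(gy)) Inf else gy[["high"]])
    })
    p <- p + ggplot2::geom_rect(
      data = rects,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax),
      inherit.aes = FALSE, colour = "red", fill = NA) +
      ggplot2::geom_text(
        data = rects,
        ggplot2::aes(x = .data$xmin * 1.5, y = .data$ymax / 1.5, label = .data$name),
        inherit.aes = FALSE, colour = "red", size = 3)
  }
  p
}
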