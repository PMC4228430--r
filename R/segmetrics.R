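#' Mean-to-median ratio (MMR)
#'
#' The MMR is a gating-free indicator of population segregation: for a
#' unimodal, near-symmetric fluorescence distribution the arithmetic mean and
#' the median coincide and the ratio is close to 1; when a minority
#' subpopulation with higher channel values appears, the mean is pulled up
#' while the median stays with the majority, and the MMR rises above 1. It
#' integrates both the relative abundance of the subpopulations and the
#' distance between their channel values, which makes it usable on raw
#' list-mode data with no operator-defined gates.
#'
#' The median of an even-sized sample is the mid-average of the two central
#' order statistics (the convention of common instrument software).
#' Statistics are computed on linear raw channel values; if you want the
#' ratio on log-transformed data use [log_mmr()], which is deliberately a
#' separately named statistic, never a default.
#'
#' @param values Numeric vector of linear channel values (non-empty).
#' @return The ratio mean/median (dimensionless).
#' @examples
#' mmr(c(1, 2, 3))   # symmetric: 1
#' mmr(c(1, 1, 10))  # right-skewed: 4
#' @export
mmr <- function(values) {
  if (length(values) == 0) {
    stop_flowseg("empty_sample", "cannot compute MMR of an empty sample")
  }
  med <- median(values)
  if (med == 0) {
    stop_flowseg("undefined_mmr",
      "median is zero: MMR undefined (degenerate or off-scale sample)")
  }
  mean(values) / med
}

#' Mean-to-median ratio on log10-transformed values
#'
#' Optional companion statistic to [mmr()]; values must be strictly positive.
#' @inheritParams mmr
#' @return mean(log10 v) / median(log10 v).
#' @export
log_mmr <- function(values) {
  if (length(values) == 0) {
    stop_flowseg("empty_sample", "cannot compute MMR of an empty sample")
  }
  if (any(values <= 0)) {
    stop_flowseg("precondition", "log_mmr requires strictly positive values")
  }
  mmr(log10(values))
}

#' Degree of segregation from two gate fractions
#'
#' `1 - |f_R1 - f_R2|` on the fractions of cells in the two subpopulation
#' gates (PI-negative healthy cells and intermediate-PI cells). The statistic
#' ranges from 0 — minimal segregation, all cells in a single gate — to 1 —
#' maximal segregation, cells equally partitioned between the two
#' subpopulations.
#'
#' Inputs are **fractions** in \[0, 1\], not percentages: on a 0-100 scale
#' the formula would leave the stated \[0, 1\] range, so percent-scale input
#' (fractions summing beyond 1) is rejected loudly.
#'
#' @param f_r1,f_r2 Fractions of analysed cells in the two gates; each in
#'   \[0, 1\], together at most 1.
#' @return Dimensionless value in \[0, 1\]; symmetric in its arguments.
#' @examples
#' degree_of_segregation(0.5, 0.5)  # equal partition: 1
#' degree_of_segregation(1, 0)      # single gate: 0
#' @export
degree_of_segregation <- function(f_r1, f_r2) {
  ok <- is.numeric(f_r1) && is.numeric(f_r2) &&
    length(f_r1) == 1 && length(f_r2) == 1 &&
    !is.na(f_r1) && !is.na(f_r2) &&
    f_r1 >= 0 && f_r1 <= 1 && f_r2 >= 0 && f_r2 <= 1 &&
    (f_r1 + f_r2) <= 1 + 1e-12
  if (!ok) {
    stop_flowseg("invalid_fraction",
      "f_r1 and f_r2 must be fractions in [0, 1] summing to at most 1 (not percentages)")
  }
  unname(1 - abs(f_r1 - f_r2))
}

#' Summarize one cytometry sample
#'
#' Applies the FSC acquisition threshold, assigns gates, and computes the
#' per-sample segregation statistics: per-channel mean, median and MMR both
#' overall and within each gate, the gate fractions, and the degree of
#' segregation from the `R1`/`R2` fractions (`NA` if the gate set has no
#' gates with those names). Gates holding fewer than 100 events have their
#' statistics flagged `low_count`: with only a handful of cells in a gate the
#' mean and median lose relevance and the per-gate MMR is unreliable.
#'
#' @param table An [event_table()].
#' @param gateset A [gate_set()].
#' @param time Sample timestamp in hours from culture start; defaults to the
#'   table's acquisition metadata.
#' @param sample_id Optional identifier.
#' @return A `sample_summary` object; see [tidy()][generics::tidy] and
#'   [glance()][generics::glance] methods.
#' @export
summarize_sample <- function(table, gateset, time = NULL, sample_id = NA_character_) {
  if (is.null(time)) time <- acquisition_meta(table)$time_h
  kept <- apply_fsc_threshold(table, gateset)
  if (nrow(kept) == 0) {
    stop_flowseg("empty_sample", "no events above the FSC threshold")
  }
  labels <- assign_gates(kept, gateset, sample_id = sample_id)
  fr <- gate_fractions(labels)
  channels <- names(kept)

  stat_block <- function(df, gate_name) {
    purrr::map_dfr(channels, function(ch) {
      v <- df[[ch]]
      med <- median(v)
      tibble(gate = gate_name, channel = ch, n = length(v),
             mean = mean(v), median = med,
             mmr = if (med == 0) NA_real_ else mean(v) / med,
             low_count = length(v) < 100)
    })
  }
  stats <- stat_block(kept, "overall")
  lev <- unique(c(gate_names(gateset), "ungated"))
  for (g in lev) {
    sub <- as.data.frame(kept)[labels$label == g, , drop = FALSE]
    if (nrow(sub) > 0) stats <- dplyr::bind_rows(stats, stat_block(sub, g))
  }

  frac_of <- function(g) {
    i <- match(g, fr$gate)
    if (is.na(i)) NA_real_ else fr$fraction[[i]]
  }
  f1 <- frac_of("R1"); f2 <- frac_of("R2")
  degree <- if (is.na(f1) || is.na(f2)) NA_real_ else degree_of_segregation(f1, f2)

  structure(list(
    time = as.numeric(time),
    sample_id = sample_id,
    n_events = nrow(table),
    n_analysed = nrow(kept),
    channels = channels,
    stats = stats,
    fractions = fr,
    degree_of_segregation = degree),
    class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf("<sample_summary: t = %s h, %d/%d events analysed, segregation = %s>\n",
              format(x$time), x$n_analysed, x$n_events,
              format(x$degree_of_segregation, digits = 3)))
  print(x$stats)
  invisible(x)
}

#' @rdname summarize_sample
#' @param x A `sample_summary`.
#' @param ... Unused.
#' @method tidy sample_summary
#' @export
tidy.sample_summary <- function(x, ...) {
  dplyr::mutate(x$stats, time = x$time, .before = 1)
}

#' @rdname summarize_sample
#' @method glance sample_summary
#' @export
glance.sample_summary <- function(x, ...) {
  ov <- x$stats[x$stats$gate == "overall", ]
  wide <- tibble(time = x$time, n_events = x$n_events, n_analysed = x$n_analysed,
                 degree_of_segregation = x$degree_of_segregation)
  for (i in seq_len(nrow(ov))) {
    wide[[paste0("mmr_", ov$channel[[i]])]] <- ov$mmr[[i]]
  }
  for (i in seq_len(nrow(x$fractions))) {
    wide[[paste0("frac_", x$fractions$gate[[i]])]] <- x$fractions$fraction[[i]]
  }
  wide
}
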