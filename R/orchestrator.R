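#' Experiment specification
#'
#' Bundles everything needed for an end-to-end multiplexed run: a simulation
#' [scenario()] (one or more parallel reactors), the [sampler_config()] of
#' the bioreactor-cytometer interface, the [gate_set()] used for analysis,
#' the experiment duration and a single global seed from which all
#' per-reactor randomness is derived.
#'
#' @param scenario A [scenario()] object.
#' @param sampler A [sampler_config()].
#' @param gateset A [gate_set()].
#' @param duration_h Experiment duration (h); defaults to the scenario's.
#' @param seed Global integer seed.
#' @return An `experiment_spec` list.
#' @export
experiment_spec <- function(scenario, sampler = sampler_config(),
                            gateset = default_gate_set(),
                            duration_h = NULL, seed = 1) {
  stopifnot(inherits(scenario, "flowseg_scenario"),
            length(scenario$reactors) >= 1)
  duration_h <- duration_h %||% scenario$duration_h
  if (!(duration_h > 0)) stop_flowseg("precondition", "duration must be > 0")
  structure(list(scenario = scenario, sampler = sampler, gateset = gateset,
                 duration_h = duration_h, seed = as.integer(seed)),
            class = "experiment_spec")
}

# stable per-reactor seed from (global seed, reactor id); independent of the
# other reactors in the spec so multiplexing does not perturb results
derive_seed <- function(global_seed, reactor_id) {
  h <- sum(utf8ToInt(as.character(reactor_id)) *
             (seq_along(utf8ToInt(as.character(reactor_id))) %% 97 + 1))
  as.integer(((global_seed %% 65521) * 40503 + h * 2017 + 12345) %% 2147483587)
}

simulate_reactor <- function(reactor, duration_h, dt) {
  # split the integration at timed interventions (instantaneous substrate
  # additions), carrying the state across segments
  ev_times <- sort(vapply(reactor$events %||% list(), `[[`, numeric(1), "time_h"))
  ev_times <- ev_times[ev_times > 0 & ev_times < duration_h]
  bounds <- unique(c(0, ev_times, duration_h))
  state <- reactor$init
  traj <- NULL
  sim <- NULL
  for (i in seq_len(length(bounds) - 1)) {
    seg_len <- bounds[i + 1] - bounds[i]
    sim <- simulate_culture(reactor$config, reactor$growth, reactor$reporter,
                            reactor$seg, init = state, duration_h = seg_len,
                            dt = dt)
    tr <- sim$trajectory
    traj <- if (is.null(traj)) tr else dplyr::bind_rows(traj, tr[-1, ])
    state <- sim$final
    for (ev in reactor$events %||% list()) {
      if (abs(ev$time_h - bounds[i + 1]) < dt / 2 && !is.null(ev$add_glucose_g)) {
        state$S <- state$S + ev$add_glucose_g / reactor$config$volume_l
      }
    }
  }
  sim$trajectory <- traj
  sim$final <- state
  sim
}

#' Run a multiplexed simulated experiment end to end
#'
#' For each reactor of the spec: simulates the culture and reporter
#' dynamics, then every sampling-cycle period plans the dilution schedule,
#' acquires a capped event sample from the current culture state, applies
#' the FSC threshold and gates, and summarizes the segregation statistics.
#' The whole run is reproducible from the global seed (per-reactor seeds are
#' derived by stable hashing of the reactor id, so adding or removing other
#' reactors does not change a reactor's results). A failure in one reactor
#' is reported with its id and timestamp and aborts that reactor only.
#'
#' @param spec An [experiment_spec()].
#' @param keep_events Keep the per-sample event tables in the result?
#' @param events_dir If non-`NULL`, write each sample as a CSV listmode file
#'   into this directory.
#' @return A list of class `flowseg_experiment`: `series` (named list of
#'   `segregation_series`, one per reactor), `sims` (the `culture_sim`s),
#'   `schedules` (last planned schedule per reactor), and `events` (if
#'   kept: nested list reactor -> sample).
#' @export
run_experiment <- function(spec, keep_events = FALSE, events_dir = NULL) {
  stopifnot(inherits(spec, "experiment_spec"))
  sc <- spec$scenario
  out_series <- list()
  out_sims <- list()
  out_sched <- list()
  out_events <- list()
  if (!is.null(events_dir) && !dir.exists(events_dir)) {
    dir.create(events_dir, recursive = TRUE)
  }
  cycle_h <- spec$sampler$cycle_period_min / 60
  sample_times <- seq(cycle_h, spec$duration_h, by = cycle_h)

  for (reactor in sc$reactors) {
    rid <- reactor$id
    res <- tryCatch({
      rseed <- derive_seed(spec$seed, rid)
      sim <- simulate_reactor(reactor, spec$duration_h, sc$dt)
      summaries <- list()
      events <- list()
      sched <- NULL
      for (k in seq_along(sample_times)) {
        tk <- sample_times[[k]]
        st <- state_at(sim, tk)
        density <- cell_density(st, reactor$growth)
        sched <- plan_cycle(spec$sampler, density)
        diluted <- attr(sched, "predicted_density")
        # arrival rate: diluted density (cells/mL) x FC flow (mL/s)
        rate <- diluted * spec$sampler$fc_flow_ul_min * 1e-3 / 60
        tbl <- acquire(function(n, s) sample_events(st, n, s),
                       spec$sampler, rate,
                       seed = (rseed + k) %% 2147483587)
        summaries[[k]] <- summarize_sample(tbl, spec$gateset, time = tk,
                                           sample_id = paste0(rid, "_", k))
        if (keep_events) events[[k]] <- tbl
        if (!is.null(events_dir)) {
          write_listmode_csv(tbl, file.path(events_dir,
            sprintf("%s_t%05.2fh.csv", rid, tk)))
        }
      }
      list(series = build_series(summaries, reactor_id = rid), sim = sim,
           sched = sched, events = events)
    }, flowseg_error = function(e) {
      warn(sprintf("reactor %s failed and was skipped: %s", rid,
                   conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      out_series[[rid]] <- res$series
      out_sims[[rid]] <- res$sim
      out_sched[[rid]] <- res$sched
      if (keep_events) out_events[[rid]] <- res$events
    }
  }
  structure(list(series = out_series, sims = out_sims, schedules = out_sched,
                 events = if (keep_events) out_events else NULL,
                 spec = spec),
            class = "flowseg_experiment")
}

#' @export
print.flowseg_experiment <- function(x, ...) {
  cat(sprintf("<flowseg_experiment: %d reactor(s), %s>\n",
              length(x$series), x$spec$scenario$name))
  for (s in x$series) print(s)
  invisible(x)
}

#' Analyse a set of recorded samples off-line
#'
#' Reads each file (FCS by `.fcs` extension, otherwise CSV listmode),
#' applies the FSC threshold and gates, summarizes, and assembles the
#' per-sample summaries into a [build_series()] time series. Files that fail
#' to parse are skipped; their errors are collected in the result's
#' `"failures"` attribute and reported as a warning, and the run continues.
#'
#' @param paths Character vector of file paths.
#' @param gateset A [gate_set()].
#' @param times Sample times (h), one per file; defaults to each file's
#'   stored acquisition time, falling back to the file's position.
#' @param reactor_id Optional reactor identifier for the series.
#' @return A `segregation_series`; failed files are listed in
#'   `attr(result, "failures")`.
#' @export
analyze_samples <- function(paths, gateset = default_gate_set(), times = NULL,
                            reactor_id = NA_character_) {
  summaries <- list()
  failures <- character(0)
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    res <- tryCatch({
      tbl <- if (grepl("\\.fcs$", p, ignore.case = TRUE)) read_fcs(p)
             else read_listmode_csv(p)
      tm <- if (!is.null(times)) times[[i]] else acquisition_meta(tbl)$time_h
      if (is.na(tm)) tm <- i
      summarize_sample(tbl, gateset, time = tm, sample_id = basename(p))
    }, error = function(e) {
      failures <<- c(failures, setNames(conditionMessage(e), p))
      NULL
    })
    if (!is.null(res)) summaries[[length(summaries) + 1]] <- res
  }
  if (length(failures)) {
    warn(sprintf("%d of %d file(s) could not be analysed: %s",
                 length(failures), length(paths),
                 paste(names(failures), collapse = ", ")))
  }
  out <- build_series(summaries, reactor_id = reactor_id)
  attr(out, "failures") <- failures
  out
}
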