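#' Automated sampler configuration
#'
#' Parameters of the bioreactor-to-cytometer interface: two peristaltic
#' pumps (sample and diluent) feeding an in-line T-mixer, propidium iodide
#' dissolved in the diluent reservoir, and a capped acquisition on a fixed
#' cycle. Defaults are the operating point of the automated protocol:
#' 32 mL/min pumps, a 15-minute sampling cycle, 33 uL/min cytometer flow,
#' 60 s acquisitions capped at 40,000 events, dilution to at most
#' 3e6 cells/mL (the instrument's linear range), 10 mg/L PI in the diluent
#' and a minimum stain contact time of 3 minutes.
#'
#' In-line dilution is modelled as duty-cycle modulation of the sampling
#' pump: the sample pump injects culture intermittently (fraction `d` of the
#' time) into the continuous diluent flow, so the delivered density is
#' `density * d*Q_s / (d*Q_s + Q_d)`. This is an interpretation of the
#' published pump-sequencing scheme (which reaches high dilution factors the
#' tubing geometry of which is not printed), not a measured fact.
#'
#' @param sample_pump_ml_min,dilution_pump_ml_min Pump rates (mL/min).
#' @param cycle_period_min Sampling cycle period (min).
#' @param fc_flow_ul_min Cytometer flow rate (uL/min).
#' @param acq_duration_s Acquisition duration (s).
#' @param event_cap Maximum recorded events per acquisition.
#' @param target_density Maximum diluted cell density (cells/mL).
#' @param pi_mg_l PI concentration in the diluent reservoir (mg/L).
#' @param min_contact_min Minimum PI contact time before acquisition (min).
#' @param duty_bounds Feasible duty-cycle range of the sampling pump.
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(sample_pump_ml_min = 32, dilution_pump_ml_min = 32,
                           cycle_period_min = 15, fc_flow_ul_min = 33,
                           acq_duration_s = 60, event_cap = 40000,
                           target_density = 3e6, pi_mg_l = 10,
                           min_contact_min = 3, duty_bounds = c(1e-4, 1)) {
  stopifnot(sample_pump_ml_min > 0, dilution_pump_ml_min > 0,
            cycle_period_min > 0, fc_flow_ul_min > 0, acq_duration_s > 0,
            event_cap >= 1, target_density > 0, min_contact_min >= 0,
            length(duty_bounds) == 2, duty_bounds[1] > 0,
            duty_bounds[2] <= 1, duty_bounds[1] <= duty_bounds[2])
  structure(list(sample_pump_ml_min = sample_pump_ml_min,
                 dilution_pump_ml_min = dilution_pump_ml_min,
                 cycle_period_min = cycle_period_min,
                 fc_flow_ul_min = fc_flow_ul_min,
                 acq_duration_s = acq_duration_s,
                 event_cap = as.integer(event_cap),
                 target_density = target_density, pi_mg_l = pi_mg_l,
                 min_contact_min = min_contact_min,
                 duty_bounds = as.numeric(duty_bounds)),
            class = "sampler_config")
}

#' Plan one automated sampling cycle
#'
#' Chooses the sampling-pump duty cycle `d` so the diluted density
#' `rho * d*Q_s / (d*Q_s + Q_d)` stays at or below the configured target
#' (the instrument's linear range), then lays out the timed actions of one
#' cycle: fill the sampling line, co-pump sample and diluent through the
#' mixer, hold for PI staining at least the minimum contact time, acquire,
#' and flush the lines before the next sample. The plan is deterministic in
#' `(config, reactor_density)`.
#'
#' When the culture is already at or below the target density the duty cycle
#' sits at its upper bound and the dilution factor is the minimum achievable
#' by 1:1 co-pumping (factor 2 with equal pump rates). When even the lowest
#' duty cycle cannot reach the target, the error reports the pre-dilution
#' factor the caller would need.
#'
#' @param config A [sampler_config()].
#' @param reactor_density Culture density (cells/mL), > 0.
#' @return A `sampling_schedule`: tibble of actions (`action`, `start_s`,
#'   `stop_s`) with attributes `duty_cycle`, `dilution_factor`,
#'   `contact_time_min`, `predicted_density`.
#' @export
plan_cycle <- function(config, reactor_density) {
  stopifnot(inherits(config, "sampler_config"))
  if (!is.numeric(reactor_density) || reactor_density <= 0) {
    stop_flowseg("precondition", "reactor_density must be > 0")
  }
  qs <- config$sample_pump_ml_min
  qd <- config$dilution_pump_ml_min
  diluted <- function(d) reactor_density * (d * qs) / (d * qs + qd)
  lo <- config$duty_bounds[1]; hi <- config$duty_bounds[2]

  if (diluted(hi) <= config$target_density) {
    d <- hi
  } else if (diluted(lo) > config$target_density) {
    need <- diluted(lo) / config$target_density
    stop_flowseg("infeasible_dilution", sprintf(
      paste0("density %.3g cells/mL cannot be diluted to %.3g cells/mL within ",
             "duty bounds; pre-dilute the sample at least %.1f-fold"),
      reactor_density, config$target_density, need))
  } else {
    # exact duty cycle hitting the target: rho*d*qs/(d*qs+qd) = target
    tgt <- config$target_density
    d <- tgt * qd / (qs * (reactor_density - tgt))
    d <- min(max(d, lo), hi)
  }

  fill_s <- 10
  mix_s <- 60
  hold_s <- config$min_contact_min * 60
  acq_s <- config$acq_duration_s
  flush_s <- 120
  actions <- tibble(
    action = c("fill-line", "co-pump/dilute", "stain-hold", "acquire", "flush"),
    start_s = cumsum(c(0, fill_s, mix_s, hold_s, acq_s)),
    stop_s = cumsum(c(fill_s, mix_s, hold_s, acq_s, flush_s)))
  total_s <- max(actions$stop_s)
  if (total_s > config$cycle_period_min * 60) {
    stop_flowseg("infeasible_schedule", sprintf(
      "cycle needs %.0f s but the period is %.0f s",
      total_s, config$cycle_period_min * 60))
  }
  # PI is in the diluent, so contact spans mixing + hold + acquisition
  contact_min <- (mix_s + hold_s + acq_s) / 60
  structure(actions,
            class = c("sampling_schedule", class(tibble())),
            duty_cycle = d,
            dilution_factor = (d * qs + qd) / (d * qs),
            contact_time_min = contact_min,
            predicted_density = diluted(d))
}

#' @export
print.sampling_schedule <- function(x, ...) {
  cat(sprintf(
    "<sampling_schedule: duty %.4g, dilution %.4gx, contact %.3g min, %.3g cells/mL>\n",
    attr(x, "duty_cycle"), attr(x, "dilution_factor"),
    attr(x, "contact_time_min"), attr(x, "predicted_density")))
  NextMethod()
}

#' Write a sampling schedule as a timed-action CSV
#' @param schedule A `sampling_schedule`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  write.table(as.data.frame(schedule), path, sep = ",", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Simulate one capped acquisition
#'
#' Event arrivals are Poisson at `arrival_rate` for up to the configured
#' acquisition duration; recording stops early at the event cap, in which
#' case the returned table's `truncated` flag is set. Events themselves are
#' drawn from `source`: either an [event_table()] (rows resampled with
#' replacement) or a function `function(n, seed)` returning an
#' [event_table()] of `n` events (e.g. a closure over [sample_events()]).
#'
#' @param source Event distribution: an [event_table()] or a
#'   `function(n, seed)`.
#' @param config A [sampler_config()].
#' @param arrival_rate Mean event arrival rate (events/s), >= 0.
#' @param seed Integer seed; the result is a pure function of
#'   `(source, config, arrival_rate, seed)`.
#' @return An [event_table()] with `duration_s`, `flow_rate_ul_min`,
#'   `event_cap` and `truncated` metadata filled in.
#' @export
acquire <- function(source, config, arrival_rate, seed = 1) {
  stopifnot(inherits(config, "sampler_config"))
  if (!is.numeric(arrival_rate) || arrival_rate < 0) {
    stop_flowseg("precondition", "arrival_rate must be >= 0")
  }
  n_arrived <- withr::with_seed(seed,
    rpois(1, arrival_rate * config$acq_duration_s))
  truncated <- n_arrived >= config$event_cap
  n_rec <- min(n_arrived, config$event_cap)

  events <- if (n_rec == 0) {
    if (is.function(source)) source(1, seed)[0, , drop = FALSE] else source[0, , drop = FALSE]
  } else if (is.function(source)) {
    source(n_rec, seed + 1L)
  } else {
    idx <- withr::with_seed(seed + 1L, sample.int(nrow(source), n_rec, replace = TRUE))
    as.data.frame(source)[idx, , drop = FALSE]
  }
  tm <- if (inherits(source, "event_table")) acquisition_meta(source)$time_h else
    if (inherits(events, "event_table")) acquisition_meta(events)$time_h else NA_real_
  event_table(as.data.frame(events, check.names = FALSE),
              time_h = tm,
              duration_s = config$acq_duration_s,
              flow_rate_ul_min = config$fc_flow_ul_min,
              event_cap = config$event_cap,
              truncated = truncated)
}

#' Reactor volumes exchanged during a stabilization period
#'
#' `stabilization_time * D`, the number of residence times (reactor volumes)
#' a chemostat has turned over — e.g. 43 h at D = 0.14 1/h is 6.02, i.e.
#' about 6 residence times.
#'
#' @param stabilization_time Time (h), >= 0.
#' @param D Dilution rate (1/h), > 0.
#' @return A list with `volumes` (the product) and `nearest` (rounded).
#' @export
residence_times <- function(stabilization_time, D) {
  if (!is.numeric(D) || D <= 0) {
    stop_flowseg("invalid_rate", "dilution rate D must be > 0")
  }
  if (stabilization_time < 0) {
    stop_flowseg("precondition", "stabilization_time must be >= 0")
  }
  v <- stabilization_time * D
  list(volumes = v, nearest = as.integer(round(v)))
}
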