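#' Growth and energy parameters of the simulated culture
#'
#' Monod growth closure with a lumped per-biomass ATP pool. The kinetic
#' defaults are conventional values for *E. coli* on glucose minimal medium
#' (they are modelling choices, not measured for any particular strain):
#' `mu_max` 0.6 1/h, `K_s` 0.05 g/L, `Y_xs` 0.5 g biomass / g glucose. The
#' ATP pool (arbitrary units, per biomass) is fed proportionally to the
#' specific substrate uptake rate and drained first-order by maintenance and
#' by heat-shock protease activity.
#'
#' @param mu_max Maximum specific growth rate (1/h) at the reference 37 C.
#' @param K_s Monod half-saturation constant for glucose (g/L).
#' @param Y_xs Biomass yield on glucose (g/g).
#' @param cells_per_g Cell number per gram dry weight (cells/g), used to
#'   convert biomass concentration to event density.
#' @param atp_yield ATP source coefficient on specific uptake (a.u. per g/g).
#' @param atp_decay Maintenance drain rate of the ATP pool (1/h).
#' @param atp_protease Additional ATP drain per unit of heat-shock protease
#'   induction above baseline (1/h).
#' @return A `growth_params` list.
#' @export
growth_params <- function(mu_max = 0.6, K_s = 0.05, Y_xs = 0.5,
                          cells_per_g = 3.6e12,
                          atp_yield = 2, atp_decay = 1.5, atp_protease = 0.15) {
  p <- list(mu_max = mu_max, K_s = K_s, Y_xs = Y_xs, cells_per_g = cells_per_g,
            atp_yield = atp_yield, atp_decay = atp_decay,
            atp_protease = atp_protease)
  if (any(unlist(p) < 0)) stop_flowseg("precondition", "growth parameters must be non-negative")
  structure(p, class = "growth_params")
}

#' Destabilized-GFP reporter parameters
#'
#' The reporter is a short-lived GFP variant carrying a C-terminal
#' degradation tag recognized by ATP-dependent proteases, expressed from a
#' growth-phase-responsive promoter whose synthesis flux scales with the
#' square of the specific growth rate. Its balance is
#'
#'   dG/dt = alpha * mu^2 - (delta_0 + h(T) * delta_max * A/(K_A + A)) * G - mu * G
#'
#' where `G` is mean per-cell GFP (a.u.), `A` the ATP pool, and `h(T)` the
#' sigma-32-like heat-shock induction factor: 1 at or below the 37 C
#' baseline; on an upshift to 42 C it spikes to `spike_fold` (default 17.5,
#' the midpoint of the reported 15-20 fold) and relaxes over about 5 minutes
#' to `plateau_fold` (default 2.5, midpoint of 2-3 fold).
#'
#' The defaults give an ATP-replete degradation rate
#' `delta_0 + delta_max = 1.0` 1/h, i.e. a half-life of `ln 2 / 1.0 = 0.69 h`
#' — under the sub-hour half-life the destabilized variant is built for.
#'
#' @param alpha Synthesis coefficient on mu^2 (a.u. h).
#' @param delta_max Maximal ATP-dependent degradation rate (1/h).
#' @param delta_0 Basal (ATP-independent) degradation rate (1/h).
#' @param K_A ATP half-saturation of the protease machinery (a.u.).
#' @param spike_fold,plateau_fold,tau_h Heat-shock induction: initial fold
#'   spike, stabilized fold, and relaxation time constant (h; the default
#'   5/180 h makes the spike decay over ~5 min).
#' @param shock_temp Temperature (deg C) at or above which the heat-shock
#'   response is triggered.
#' @param fl1_sdlog_shock Log-sd of the sampled FL1 distribution after a heat
#'   shock (the GFP histogram widens when degradation sets in).
#' @return A `reporter_params` list.
#' @export
reporter_params <- function(alpha = 2000, delta_max = 0.9, delta_0 = 0.1,
                            K_A = 0.2, spike_fold = 17.5, plateau_fold = 2.5,
                            tau_h = 5 / 180, shock_temp = 42,
                            fl1_sdlog_shock = 0.6) {
  p <- list(alpha = alpha, delta_max = delta_max, delta_0 = delta_0, K_A = K_A,
            spike_fold = spike_fold, plateau_fold = plateau_fold, tau_h = tau_h,
            shock_temp = shock_temp, fl1_sdlog_shock = fl1_sdlog_shock)
  if (any(unlist(p) < 0)) stop_flowseg("precondition", "reporter parameters must be non-negative")
  structure(p, class = "reporter_params")
}

#' Subpopulation-segregation parameters
#'
#' Dynamics of the intermediate-permeability (R2) fraction: under sustained
#' substrate limitation cells permeabilize their membrane and the R2
#' fraction relaxes first-order (time constant `tau_h`) toward a target that
#' interpolates between `f2_min` (unstressed cultures carry under 5 percent
#' intermediate cells) and `f2_max` (default 0.5, at which the degree of
#' segregation reaches its maximum of 1).
#'
#' @param f2_min Minimum (unstressed) R2 fraction.
#' @param f2_max Maximum R2 fraction under full limitation.
#' @param tau_h Relaxation time constant (h).
#' @return A `seg_params` list.
#' @export
seg_params <- function(f2_min = 0.03, f2_max = 0.5, tau_h = 1) {
  stopifnot(f2_min >= 0, f2_max <= 1, f2_min <= f2_max, tau_h > 0)
  structure(list(f2_min = f2_min, f2_max = f2_max, tau_h = tau_h),
            class = "seg_params")
}

#' Bioreactor phase and configuration
#'
#' A reactor runs an ordered schedule of phases: `batch` (no feed),
#' `chemostat` at dilution rate `D`, or `chemostat_pulses` — chemostat plus
#' instantaneous glucose additions of `pulse_g` grams every
#' `pulse_period_min` minutes (first pulse one period after the phase
#' starts). The temperature schedule is either a constant or a step function
#' given as breakpoints.
#'
#' @param mode `"batch"`, `"chemostat"` or `"chemostat_pulses"`.
#' @param start_h Phase start time (h); phases must start at strictly
#'   increasing times and the first phase at 0.
#' @param D Dilution rate (1/h) for chemostat modes.
#' @param pulse_g Glucose mass per pulse (g).
#' @param pulse_period_min Pulse period (min).
#' @return A `reactor_phase` list.
#' @export
phase <- function(mode = c("batch", "chemostat", "chemostat_pulses"),
                  start_h = 0, D = 0, pulse_g = 0, pulse_period_min = 15) {
  mode <- match.arg(mode)
  if (D < 0) stop_flowseg("precondition", "dilution rate must be >= 0")
  structure(list(mode = mode, start_h = start_h, D = D, pulse_g = pulse_g,
                 pulse_period_min = pulse_period_min),
            class = "reactor_phase")
}

#' @rdname phase
#' @param phases List of [phase()]s.
#' @param temperature Either a single temperature (deg C) or a data frame
#'   with columns `time_h`, `temp_c` defining a step schedule.
#' @param feed_glucose Feed glucose concentration (g/L) for chemostat phases.
#' @param volume_l Working volume (L).
#' @export
reactor_config <- function(phases = list(phase("batch", 0)), temperature = 37,
                           feed_glucose = 5, volume_l = 1) {
  stopifnot(length(phases) >= 1)
  starts <- vapply(phases, `[[`, numeric(1), "start_h")
  if (starts[1] != 0 || (length(starts) > 1 && any(diff(starts) <= 0))) {
    stop_flowseg("precondition",
      "phase start times must begin at 0 and be strictly increasing")
  }
  structure(list(phases = phases, temperature = temperature,
                 feed_glucose = feed_glucose, volume_l = volume_l),
            class = "reactor_config")
}

phase_at <- function(config, t) {
  starts <- vapply(config$phases, `[[`, numeric(1), "start_h")
  config$phases[[max(which(starts <= t + 1e-12))]]
}

temperature_at <- function(config, t) {
  tc <- config$temperature
  if (is.numeric(tc) && length(tc) == 1) return(tc)
  i <- findInterval(t + 1e-12, tc$time_h)
  if (i < 1) tc$temp_c[[1]] else tc$temp_c[[i]]
}

# multiplicative temperature correction of mu_max, anchored so growth is
# slowest at 30 C and fastest at 42 C among the studied temperatures
temp_growth_factor <- function(temp_c) {
  stats::approx(x = c(20, 30, 37, 42, 47), y = c(0.2, 0.6, 1, 1.15, 0.4),
                xout = temp_c, rule = 2)$y
}

# thermal efficiency of net reporter synthesis: near heat-shock temperatures
# the observed GFP signal drops even though growth is fastest, so the
# effective mu^2 synthesis flux is strongly reduced above 37 C
synth_temp_factor <- function(temp_c) {
  stats::approx(x = c(37, 40, 42), y = c(1, 0.5, 0.15), xout = temp_c,
                rule = 2)$y
}

#' Sigma-32-like heat-shock induction factor
#'
#' 1 with no heat shock; after an upshift to `shock_temp` it starts at
#' `spike_fold` and relaxes exponentially (time constant `tau_h`) to
#' `plateau_fold`.
#'
#' @param temp_c Current temperature (deg C).
#' @param heat_time_h Time since the upshift (h), `NA` if none occurred.
#' @param params A [reporter_params()].
#' @return Dimensionless induction factor >= 1.
#' @export
heat_induction <- function(temp_c, heat_time_h, params = reporter_params()) {
  if (is.na(heat_time_h) || temp_c < params$shock_temp) return(1)
  params$plateau_fold +
    (params$spike_fold - params$plateau_fold) * exp(-heat_time_h / params$tau_h)
}

#' State of one simulated culture
#'
#' Lumped mechanistic state: biomass `X` (g dry weight / L), residual glucose
#' `S` (g/L), specific growth rate `mu` (1/h), per-biomass ATP pool `A`
#' (a.u.), mean per-cell GFP `G` (a.u.), and the subpopulation split
#' `f_r1`/`f_r2`/`f_r3` (healthy / intermediate PI uptake / damaged; must sum
#' to 1). Each subpopulation carries a log-normal FL3 location/scale used
#' when cytometry events are sampled from the state.
#'
#' @param time Time (h).
#' @param X Biomass (g/L).
#' @param S Glucose (g/L).
#' @param A ATP pool (a.u.).
#' @param G Mean per-cell GFP (a.u.).
#' @param mu Specific growth rate (1/h).
#' @param f_r1,f_r2,f_r3 Subpopulation fractions (sum to 1).
#' @param fl3_meanlog,fl3_sdlog Named numeric vectors (`R1`, `R2`, `R3`) of
#'   log-normal FL3 parameters per subpopulation.
#' @param fl1_sdlog Log-sd of the sampled FL1 distribution.
#' @param heat_time_h Time since a 42 C upshift (h); `NA` if none.
#' @return A `culture_state` list.
#' @export
culture_state <- function(time = 0, X = 0.05, S = 5, A = 1, G = 20, mu = 0,
                          f_r1 = 0.97, f_r2 = 0.03, f_r3 = 0,
                          fl3_meanlog = c(R1 = log(150), R2 = log(2000),
                                          R3 = log(10^4.5)),
                          fl3_sdlog = c(R1 = 0.4, R2 = 0.5, R3 = 0.35),
                          fl1_sdlog = 0.35, heat_time_h = NA_real_) {
  s <- structure(list(time = time, X = X, S = S, A = A, G = G, mu = mu,
                      f_r1 = f_r1, f_r2 = f_r2, f_r3 = f_r3,
                      fl3_meanlog = fl3_meanlog, fl3_sdlog = fl3_sdlog,
                      fl1_sdlog = fl1_sdlog, heat_time_h = heat_time_h),
                 class = "culture_state")
  validate_state(s)
  s
}

validate_state <- function(s) {
  if (any(c(s$X, s$S, s$A, s$G) < 0)) {
    stop_flowseg("integration_failure",
      "state became negative; reduce the integration step dt")
  }
  f <- c(s$f_r1, s$f_r2, s$f_r3)
  if (any(f < -1e-9) || abs(sum(f) - 1) > 1e-9) {
    stop_flowseg("integration_failure", "subpopulation fractions must sum to 1")
  }
  invisible(s)
}

#' Event density of a culture state
#' @param state A [culture_state()].
#' @param growth A [growth_params()] (for the cells-per-gram conversion).
#' @return Cell density in cells/mL.
#' @export
cell_density <- function(state, growth = growth_params()) {
  state$X * growth$cells_per_g / 1000
}

#' Advance the culture mass balances by one step
#'
#' Explicit fixed-step integration (forward Euler, `dt <= 0.01` h) of Monod
#' growth with the phase-appropriate reactor terms:
#'
#' * `mu = mu_max * g(T) * S / (K_s + S)`
#' * batch: `dX/dt = mu X`, `dS/dt = -mu X / Y_xs`
#' * chemostat adds `-D X` and `D (S_feed - S)`
#' * glucose pulses add `pulse_g / volume` to `S` instantaneously at their
#'   scheduled times
#' * ATP: `dA/dt = atp_yield * q_s - (atp_decay + atp_protease (h(T)-1)) A`
#'   with `q_s = mu / Y_xs`
#'
#' The step errors out (rather than silently clamping) if any state variable
#' goes negative, signalling the caller to reduce `dt`.
#'
#' @param state A [culture_state()].
#' @param config A [reactor_config()].
#' @param growth A [growth_params()].
#' @param dt Step (h), `0 < dt <= 0.01`.
#' @param reporter A [reporter_params()] (for the heat-shock constants used
#'   in the ATP drain).
#' @return The advanced `culture_state`.
#' @export
step_culture <- function(state, config, growth = growth_params(), dt = 0.005,
                         reporter = reporter_params()) {
  if (!(dt > 0 && dt <= 0.01)) {
    stop_flowseg("precondition", "dt must satisfy 0 < dt <= 0.01 h")
  }
  t <- state$time
  ph <- phase_at(config, t)
  temp <- temperature_at(config, t)

  # heat-shock clock
  if (temp >= reporter$shock_temp) {
    state$heat_time_h <- if (is.na(state$heat_time_h)) 0 else state$heat_time_h + dt
  }

  D <- if (ph$mode == "batch") 0 else ph$D
  S_feed <- config$feed_glucose
  mu <- growth$mu_max * temp_growth_factor(temp) * state$S / (growth$K_s + state$S)
  q_s <- mu / growth$Y_xs
  h <- heat_induction(temp, state$heat_time_h, reporter)

  X <- state$X + (mu - D) * state$X * dt
  S <- state$S + (-q_s * state$X + D * (S_feed - state$S)) * dt
  A <- state$A + (growth$atp_yield * q_s -
                    (growth$atp_decay + growth$atp_protease * (h - 1)) * state$A) * dt

  # scheduled instantaneous pulses crossed in (t, t + dt]
  if (ph$mode == "chemostat_pulses" && ph$pulse_g > 0) {
    per <- ph$pulse_period_min / 60
    k1 <- floor((t - ph$start_h) / per + 1e-9)
    k2 <- floor((t + dt - ph$start_h) / per + 1e-9)
    if (k2 > k1) S <- S + (k2 - k1) * ph$pulse_g / config$volume_l
  }

  state$time <- t + dt
  state$X <- X
  state$S <- S
  state$A <- A
  state$mu <- mu
  validate_state(state)
  state
}

#' Advance the GFP reporter balance by one step
#'
#' Forward-Euler step of the reporter ODE (see [reporter_params()]); also
#' widens the sampled FL1 distribution once a heat shock has occurred.
#'
#' The `mu^2` synthesis flux carries a thermal efficiency factor (1 at or
#' below 37 C, strongly reduced at 42 C): near heat-shock temperatures the
#' observed reporter signal falls even while growth accelerates, so net
#' synthesis cannot follow `mu^2` alone there.
#'
#' @param state A [culture_state()] (its `mu` and `A` drive the step).
#' @param params A [reporter_params()].
#' @param temperature Current temperature (deg C).
#' @param dt Step (h), `0 < dt <= 0.01`.
#' @return The advanced `culture_state`.
#' @export
step_reporter <- function(state, params = reporter_params(), temperature = 37,
                          dt = 0.005) {
  if (!(dt > 0 && dt <= 0.01)) {
    stop_flowseg("precondition", "dt must satisfy 0 < dt <= 0.01 h")
  }
  h <- heat_induction(temperature, state$heat_time_h, params)
  delta <- params$delta_0 + h * params$delta_max * state$A / (params$K_A + state$A)
  synth <- params$alpha * state$mu^2 * synth_temp_factor(temperature)
  G <- state$G + (synth - (delta + state$mu) * state$G) * dt
  state$G <- G
  if (!is.na(state$heat_time_h)) {
    state$fl1_sdlog <- max(state$fl1_sdlog, params$fl1_sdlog_shock)
  }
  validate_state(state)
  state
}

#' Relax the subpopulation split toward the limitation-set target
#'
#' The intermediate (R2) fraction relaxes first-order toward
#' `f2_min + (f2_max - f2_min) * limitation`; the healthy fraction absorbs
#' the balance. The damaged fraction `f_r3` is untouched — it changes only
#' through an explicit [kill_culture()] event (the 65 C control).
#'
#' @param state A [culture_state()].
#' @param limitation Dimensionless limitation signal in \[0, 1\] (e.g.
#'   `1 - S / (S + K_s)`).
#' @param dt Step (h).
#' @param seg A [seg_params()].
#' @return The advanced `culture_state`.
#' @export
update_segregation <- function(state, limitation, dt = 0.005, seg = seg_params()) {
  if (!is.numeric(limitation) || limitation < 0 || limitation > 1) {
    stop_flowseg("precondition", "limitation signal must be in [0, 1]")
  }
  avail <- 1 - state$f_r3
  target <- min(seg$f2_min + (seg$f2_max - seg$f2_min) * limitation, avail)
  f2 <- state$f_r2 + (target - state$f_r2) * (1 - exp(-dt / seg$tau_h))
  state$f_r2 <- f2
  state$f_r1 <- 1 - f2 - state$f_r3
  validate_state(state)
  state
}

#' Kill a fraction of the culture (65 C control)
#'
#' Moves `fraction` of the live (R1 + R2) cells into the damaged (R3,
#' maximal PI uptake) subpopulation, emulating the heat-inactivation control
#' (65 C for 30 minutes) used to anchor the damaged-cell gate.
#'
#' @param state A [culture_state()].
#' @param fraction Fraction of live cells to kill, in \[0, 1\].
#' @return The modified `culture_state`.
#' @export
kill_culture <- function(state, fraction = 1) {
  stopifnot(fraction >= 0, fraction <= 1)
  live <- state$f_r1 + state$f_r2
  state$f_r3 <- state$f_r3 + fraction * live
  state$f_r1 <- state$f_r1 * (1 - fraction)
  state$f_r2 <- state$f_r2 * (1 - fraction)
  validate_state(state)
  state
}

#' Draw cytometry events from a culture state
#'
#' Samples `n` events: subpopulation membership is multinomial on
#' `(f_r1, f_r2, f_r3)`; FL3 is log-normal with the member subpopulation's
#' location/scale; FL1 is log-normal centred on the current mean per-cell
#' GFP with the state's spread (widened after heat shock); FSC/SSC are
#' filler scatter distributions placed almost entirely above the 80,000 FSC
#' acquisition threshold. The draw is a pure function of `(state, n, seed)`.
#'
#' @param state A [culture_state()].
#' @param n Number of events (>= 1).
#' @param seed Integer seed.
#' @return An [event_table()] with channels `FSC`, `SSC`, `FL1`, `FL3`.
#' @export
sample_events <- function(state, n, seed) {
  if (!is.numeric(n) || n < 1) {
    stop_flowseg("invalid_size", "n must be at least 1")
  }
  n <- as.integer(n)
  withr::with_seed(seed, {
    comp <- sample.int(3L, n, replace = TRUE,
                       prob = c(state$f_r1, state$f_r2, state$f_r3))
    fl3 <- rlnorm(n, meanlog = state$fl3_meanlog[comp],
                  sdlog = state$fl3_sdlog[comp])
    fl1 <- rlnorm(n, meanlog = log(max(state$G, 1e-3)), sdlog = state$fl1_sdlog)
    fsc <- rlnorm(n, meanlog = log(2e5), sdlog = 0.25)
    ssc <- rlnorm(n, meanlog = log(5e4), sdlog = 0.3)
    event_table(tibble(FSC = fsc, SSC = ssc, FL1 = fl1, FL3 = fl3),
                time_h = state$time)
  })
}

#' Generate a heat-killed control sample
#'
#' Convenience wrapper: fully kills a copy of `state` and samples `n` events
#' from it, for calibrating the damaged-cell gate with
#' [calibrate_damaged_gate()].
#'
#' @param n Number of events.
#' @param seed Integer seed.
#' @param state Base [culture_state()].
#' @return An [event_table()].
#' @export
heat_killed_control <- function(n = 10000, seed = 1, state = culture_state()) {
  sample_events(kill_culture(state, 1), n, seed)
}

#' Simulate a culture trajectory
#'
#' Steps the culture, reporter and segregation balances jointly from `init`
#' over `duration_h` hours with a fixed step `dt`, using
#' `limitation = 1 - S / (S + K_s)` as the segregation drive. Returns the
#' recorded trajectory and the final state.
#'
#' @param config A [reactor_config()].
#' @param growth,reporter,seg Parameter sets.
#' @param init Initial [culture_state()].
#' @param duration_h Duration (h).
#' @param dt Step (h), `<= 0.01`.
#' @return A list of class `culture_sim` with `trajectory` (a tibble: time,
#'   X, S, mu, A, G, f_r1, f_r2, f_r3, temp_c, fl1_sdlog, heat_time_h) and
#'   `final` (the end-state).
#' @export
simulate_culture <- function(config, growth = growth_params(),
                             reporter = reporter_params(), seg = seg_params(),
                             init = culture_state(), duration_h = 10,
                             dt = 0.005) {
  n_steps <- ceiling(duration_h / dt)
  cols <- c("time", "X", "S", "mu", "A", "G", "f_r1", "f_r2", "f_r3",
            "temp_c", "fl1_sdlog", "heat_time_h")
  rec <- matrix(NA_real_, nrow = n_steps + 1, ncol = length(cols),
                dimnames = list(NULL, cols))
  state <- init
  snap <- function(s) c(s$time, s$X, s$S, s$mu, s$A, s$G, s$f_r1, s$f_r2,
                        s$f_r3, temperature_at(config, s$time), s$fl1_sdlog,
                        s$heat_time_h)
  rec[1, ] <- snap(state)
  for (i in seq_len(n_steps)) {
    temp <- temperature_at(config, state$time)
    state <- step_culture(state, config, growth, dt, reporter)
    state <- step_reporter(state, reporter, temp, dt)
    lim <- 1 - state$S / (state$S + growth$K_s)
    state <- update_segregation(state, lim, dt, seg)
    rec[i + 1, ] <- snap(state)
  }
  structure(list(trajectory = as_tibble(as.data.frame(rec)),
                 final = state, config = config, growth = growth,
                 reporter = reporter, seg = seg),
            class = "culture_sim")
}

#' @export
print.culture_sim <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf("<culture_sim: %g h in %d steps; final X = %.3g g/L, G = %.3g a.u.>\n",
              max(tr$time), nrow(tr) - 1, x$final$X, x$final$G))
  invisible(x)
}

#' Reconstruct the culture state at a given time of a simulation
#'
#' Takes the recorded trajectory row nearest to `time` and rebuilds a full
#' [culture_state()] (subpopulation FL3 parameters are those of the
#' simulation's states).
#'
#' @param sim A `culture_sim` from [simulate_culture()].
#' @param time Time (h).
#' @return A `culture_state`.
#' @export
state_at <- function(sim, time) {
  tr <- sim$trajectory
  i <- which.min(abs(tr$time - time))
  culture_state(time = tr$time[[i]], X = tr$X[[i]], S = tr$S[[i]],
                A = tr$A[[i]], G = tr$G[[i]], mu = tr$mu[[i]],
                f_r1 = tr$f_r1[[i]], f_r2 = tr$f_r2[[i]], f_r3 = tr$f_r3[[i]],
                fl3_meanlog = sim$final$fl3_meanlog,
                fl3_sdlog = sim$final$fl3_sdlog,
                fl1_sdlog = tr$fl1_sdlog[[i]],
                heat_time_h = tr$heat_time_h[[i]])
}

#' Plot a simulated culture trajectory
#'
#' @param object A `culture_sim`.
#' @param ... Unused.
#' @return A ggplot object with one panel per state variable.
#' @method autoplot culture_sim
#' @export
autoplot.culture_sim <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$trajectory[, c("time", "X", "S", "mu", "A", "G", "f_r2")],
    -"time", names_to = "variable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = NULL) +
    ggplot2::theme_minimal()
}
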