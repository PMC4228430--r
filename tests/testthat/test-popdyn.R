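test_that("a chemostat settles at the analytic residual substrate", {
  gp <- growth_params()
  D <- 0.14
  cfg <- reactor_config(phases = list(phase("chemostat", 0, D = D)))
  sim <- simulate_culture(cfg, gp, duration_h = 60, dt = 0.01,
                          init = culture_state(X = 1, S = 0.1))
  s_star <- gp$K_s * D / (gp$mu_max - D)
  expect_equal(sim$final$S, s_star, tolerance = 0.01)
  expect_equal(sim$final$mu, D, tolerance = 0.01)
  # biomass at the steady state matches the yield balance
  expect_equal(sim$final$X, gp$Y_xs * (5 - s_star), tolerance = 0.01)
})

test_that("starvation is a fixed point and super-critical dilution washes out", {
  cfg0 <- reactor_config(phases = list(phase("batch", 0)))
  st <- culture_state(X = 1, S = 0, G = 10)
  sim <- simulate_culture(cfg0, duration_h = 2, dt = 0.01, init = st)
  expect_equal(sim$final$X, 1)
  expect_equal(sim$final$mu, 0)

  # D > mu_max: washout, monotone decline after the initial transient
  cfgw <- reactor_config(phases = list(phase("chemostat", 0, D = 0.8)))
  simw <- simulate_culture(cfgw, duration_h = 30, dt = 0.01,
                           init = culture_state(X = 1, S = 0.1))
  x <- simw$trajectory$X
  expect_lt(simw$final$X, 1e-2)
  late <- x[simw$trajectory$time > 5]
  expect_true(all(diff(late) <= 0))
})

test_that("batch growth conserves the yield-weighted mass balance", {
  gp <- growth_params()
  cfg <- reactor_config(phases = list(phase("batch", 0)))
  init <- culture_state(X = 0.05, S = 5)
  sim <- simulate_culture(cfg, gp, duration_h = 12, dt = 0.005, init = init)
  tr <- sim$trajectory
  resid <- gp$Y_xs * (init$S - tr$S) - (tr$X - init$X)
  expect_lt(max(abs(resid)), 1e-8)
  # the culture actually grew and exhausted the glucose
  expect_gt(sim$final$X, 2)
  expect_lt(sim$final$S, 0.01)
})

test_that("the reporter reaches its analytic steady state under constant drive", {
  rp <- reporter_params()
  gp <- growth_params()
  # glucose-saturated chemostat pins mu and the ATP pool at constants
  cfg <- reactor_config(phases = list(phase("chemostat", 0, D = 0.3)),
                        feed_glucose = 50)
  sim <- simulate_culture(cfg, gp, rp, duration_h = 80, dt = 0.01,
                          init = culture_state(X = 1, S = 10, G = 1))
  st <- sim$final
  delta <- rp$delta_0 + rp$delta_max * st$A / (rp$K_A + st$A)
  g_star <- rp$alpha * st$mu^2 / (delta + st$mu)
  expect_equal(st$G, g_star, tolerance = 0.01)
})

test_that("with synthesis off the reporter decays exponentially at the set rate", {
  # delta = ln 2 / 0.8 h: G halves every 0.8 h
  rp <- reporter_params(delta_0 = log(2) / 0.8, delta_max = 0)
  st <- culture_state(X = 1, S = 0, G = 100, mu = 0)
  dt <- 0.005
  for (i in seq_len(0.8 / dt)) st <- step_reporter(st, rp, 37, dt)
  expect_equal(st$G, 50, tolerance = 0.01)
  for (i in seq_len(0.8 / dt)) st <- step_reporter(st, rp, 37, dt)
  expect_equal(st$G, 25, tolerance = 0.01)
})

test_that("default degradation gives a sub-hour half-life when ATP is replete", {
  rp <- reporter_params()
  st <- culture_state(X = 1, S = 0, G = 100, A = 10, mu = 0)
  dt <- 0.005
  t <- 0
  while (st$G > 50 && t < 2) {
    st$A <- 10  # hold the pool replete
    st <- step_reporter(st, rp, 37, dt)
    t <- t + dt
  }
  expect_lte(t, 1)
  expect_equal(t, log(2) / (rp$delta_0 + rp$delta_max * 10 / (rp$K_A + 10)),
               tolerance = 0.02)
})

test_that("heat-shock induction spikes 15-20 fold and relaxes to 2-3 fold", {
  rp <- reporter_params()
  expect_equal(heat_induction(42, 0, rp), 17.5)
  expect_equal(heat_induction(37, 0.5, rp), 1)   # below the shock temperature
  expect_equal(heat_induction(42, NA, rp), 1)    # no upshift occurred
  h5 <- heat_induction(42, 5 / 60, rp)
  expect_lt(h5, 3.5)
  expect_gt(h5, 2.5)
  h <- vapply(seq(0, 0.5, by = 0.01), function(t) heat_induction(42, t, rp),
              numeric(1))
  expect_true(all(diff(h) < 0))
  expect_equal(h[length(h)], rp$plateau_fold, tolerance = 1e-3)
})

test_that("the R2 fraction relaxes between its configured extremes", {
  sp <- seg_params()
  dt <- 0.01
  st <- culture_state(f_r1 = 0.6, f_r2 = 0.4, f_r3 = 0)
  for (i in seq_len(10 / dt)) st <- update_segregation(st, 0, dt, sp)
  expect_equal(st$f_r2, sp$f2_min, tolerance = 1e-3)
  expect_lt(st$f_r2, 0.05)

  st2 <- culture_state()
  for (i in seq_len(10 / dt)) st2 <- update_segregation(st2, 1, dt, sp)
  expect_equal(st2$f_r2, sp$f2_max, tolerance = 1e-3)
  expect_equal(degree_of_segregation(st2$f_r1, st2$f_r2), 1, tolerance = 5e-3)

  expect_error(update_segregation(st, 1.5), class = "flowseg_error_precondition")
})

test_that("segregation relaxation matches the discrete recurrence exactly", {
  sp <- seg_params(f2_min = 0.02, f2_max = 0.45, tau_h = 0.7)
  dt <- 0.01
  lim_seq <- rep(c(1, 0), each = 50, times = 3)
  st <- culture_state()
  f2 <- st$f_r2
  for (lim in lim_seq) {
    st <- update_segregation(st, lim, dt, sp)
    target <- sp$f2_min + (sp$f2_max - sp$f2_min) * lim
    f2 <- f2 + (target - f2) * (1 - exp(-dt / sp$tau_h))
  }
  expect_equal(st$f_r2, f2, tolerance = 1e-12)
  expect_equal(st$f_r1 + st$f_r2 + st$f_r3, 1, tolerance = 1e-12)
})

test_that("killing the culture moves all cells into the damaged band", {
  st <- kill_culture(culture_state(), 1)
  expect_equal(st$f_r3, 1)
  expect_equal(st$f_r1, 0)
  half <- kill_culture(culture_state(f_r1 = 0.8, f_r2 = 0.2, f_r3 = 0), 0.5)
  expect_equal(half$f_r3, 0.5)
  expect_equal(half$f_r1, 0.4)
})

test_that("event sampling is seed-deterministic and respects degenerate mixtures", {
  st <- culture_state()
  a <- sample_events(st, 2000, seed = 99)
  b <- sample_events(st, 2000, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c_ <- sample_events(st, 2000, seed = 100)
  expect_false(isTRUE(all.equal(a$FL3, c_$FL3)))

  # f_r1 = 1: every event lands in the R1 band
  pure <- sample_events(culture_state(f_r1 = 1, f_r2 = 0, f_r3 = 0),
                        5000, seed = 4)
  lab <- assign_gates(pure, default_gate_set())
  above <- lab$label != "below-threshold"
  expect_gt(mean(lab$label[above] == "R1"), 0.999)

  expect_error(sample_events(st, 0, seed = 1), class = "flowseg_error_invalid_size")
})

test_that("a glucose pulse after heat shock accelerates reporter loss", {
  # two identical cultures shocked to 42 C at 4.5 h; one then gets glucose
  temp_sched <- data.frame(time_h = c(0, 4.5), temp_c = c(30, 42))
  cfg <- reactor_config(phases = list(phase("batch", 0)),
                        temperature = temp_sched, feed_glucose = 5,
                        volume_l = 0.2)
  # heavy inoculum: the batch glucose is exhausted before the 4.5 h shock,
  # so the unpulsed reactor sits starved (no ATP, proteases idle)
  base <- simulate_culture(cfg, duration_h = 4.5, dt = 0.005,
                           init = culture_state(X = 0.7, S = 5))
  g_shock <- base$final$G

  # finer step: the pulse makes the substrate balance stiff at high biomass
  run_on <- function(state) {
    simulate_culture(cfg, duration_h = 2.5, dt = 0.002, init = state)
  }
  no_pulse <- run_on(base$final)
  pulsed_state <- base$final
  pulsed_state$S <- pulsed_state$S + 2 / 0.2
  with_pulse <- run_on(pulsed_state)

  drop_pulse <- 1 - with_pulse$final$G / g_shock
  drop_none <- 1 - no_pulse$final$G / g_shock
  expect_gt(drop_pulse, drop_none)  # ATP fuels the proteases
  expect_lt(with_pulse$final$G, no_pulse$final$G)
})

test_that("integration guards reject oversized steps and negative states", {
  cfg <- reactor_config(phases = list(phase("batch", 0)))
  expect_error(step_culture(culture_state(), cfg, dt = 0.5),
               class = "flowseg_error_precondition")
  expect_error(step_reporter(culture_state(), dt = 0),
               class = "flowseg_error_precondition")
  expect_error(culture_state(X = -1), class = "flowseg_error_integration_failure")
  expect_error(culture_state(f_r1 = 0.5, f_r2 = 0.2, f_r3 = 0.2),
               class = "flowseg_error_integration_failure")
})
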