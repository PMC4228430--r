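test_that("FSC threshold is inclusive at the boundary and preserves order", {
  tbl <- event_table(data.frame(FSC = c(79999, 80000, 80001),
                                FL3 = c(1, 2, 3)),
                     time_h = 1, truncated = FALSE)
  kept <- apply_fsc_threshold(tbl, 80000)
  expect_equal(n_events(kept), 2L)
  expect_equal(kept$FL3, c(2, 3))
  expect_equal(acquisition_meta(kept)$time_h, 1)

  # threshold 0 is the identity
  expect_equal(n_events(apply_fsc_threshold(tbl, 0)), 3L)

  # brute-force count at an empirical percentile
  big <- make_table(1000, seed = 3)
  thr <- as.numeric(quantile(big$FSC, 0.30))
  expect_equal(n_events(apply_fsc_threshold(big, thr)), sum(big$FSC >= thr))

  no_fsc <- event_table(data.frame(FL3 = 1:3))
  expect_error(apply_fsc_threshold(no_fsc, 1),
               class = "flowseg_error_missing_channel")
})

test_that("gate assignment uses half-open bounds and priority for overlaps", {
  gs <- gate_set(gate("R1", FL3 = c(0, 100), priority = 1L),
                 gate("R2", FL3 = c(100, 1000), priority = 2L),
                 fsc_threshold = 0)
  tbl <- event_table(data.frame(FSC = rep(1e5, 3), FL3 = c(99.999, 100, 999.999)))
  lab <- assign_gates(tbl, gs)
  expect_equal(lab$label, c("R1", "R2", "R2"))

  # overlapping gates: larger priority wins
  gs2 <- gate_set(gate("low", FL3 = c(0, 1000), priority = 1L),
                  gate("high", FL3 = c(50, 500), priority = 7L),
                  fsc_threshold = 0)
  lab2 <- assign_gates(event_table(data.frame(FSC = 1e5, FL3 = 100)), gs2)
  expect_equal(lab2$label, "high")

  # an all-space gate captures every above-threshold event
  gs3 <- gate_set(gate("all", FL3 = c(0, Inf), priority = 1L), fsc_threshold = 80000)
  tbl3 <- make_table(200, seed = 9)
  lab3 <- assign_gates(tbl3, gs3)
  expect_true(all(lab3$label[tbl3$FSC >= 80000] == "all"))
  expect_true(all(lab3$label[tbl3$FSC < 80000] == "below-threshold"))

  expect_error(
    assign_gates(event_table(data.frame(FSC = 1e5)), gs),
    class = "flowseg_error_missing_channel")
})

test_that("gate counts match brute-force membership on a 10,000-event mixture", {
  st <- culture_state(f_r1 = 0.6, f_r2 = 0.3, f_r3 = 0.1)
  tbl <- sample_events(st, 10000, seed = 13)
  gs <- default_gate_set()
  lab <- assign_gates(tbl, gs)
  above <- tbl$FSC >= gs$fsc_threshold
  for (g in gs$gates) {
    b <- g$bounds$FL3
    brute <- sum(above & tbl$FL3 >= b[["low"]] & tbl$FL3 < b[["high"]])
    expect_equal(sum(lab$label == g$name), brute, info = g$name)
  }
  # labelling is a partition
  expect_equal(nrow(lab), n_events(tbl))
  expect_true(all(lab$label %in% c("R1", "R2", "R3", "ungated", "below-threshold")))
})

test_that("gate fractions are computed over above-threshold events and sum to 1", {
  gs <- gate_set(gate("R1", FL3 = c(0, 100), priority = 1L),
                 gate("R2", FL3 = c(100, 1000), priority = 2L),
                 fsc_threshold = 80000)
  tbl <- event_table(data.frame(FSC = c(1e5, 1e5, 1e5, 1e5, 10),
                                FL3 = c(10, 20, 150, 5000, 50)))
  fr <- gate_fractions(assign_gates(tbl, gs))
  expect_equal(fr$fraction[fr$gate == "R1"], 0.5)
  expect_equal(fr$fraction[fr$gate == "R2"], 0.25)
  expect_equal(fr$fraction[fr$gate == "ungated"], 0.25)
  expect_equal(sum(fr$fraction), 1, tolerance = 1e-12)

  # all events in one gate
  one <- event_table(data.frame(FSC = rep(1e5, 4), FL3 = rep(10, 4)))
  fr1 <- gate_fractions(assign_gates(one, gs))
  expect_equal(fr1$fraction[fr1$gate == "R1"], 1)

  # permutation invariance
  perm <- withr::with_seed(5, sample.int(n_events(tbl)))
  tblp <- event_table(as.data.frame(tbl)[perm, ])
  frp <- gate_fractions(assign_gates(tblp, gs))
  expect_equal(dplyr::arrange(frp, gate), dplyr::arrange(fr, gate))

  # no above-threshold events
  low <- event_table(data.frame(FSC = c(1, 2), FL3 = c(1, 2)))
  expect_error(gate_fractions(assign_gates(low, gs)),
               class = "flowseg_error_empty_sample")
})

test_that("a 40,000-event sample recovers the generator's R2 fraction within 3 SE", {
  st <- culture_state(f_r1 = 0.70, f_r2 = 0.30, f_r3 = 0)
  tbl <- sample_events(st, 40000, seed = 5)
  fr <- gate_fractions(assign_gates(tbl, default_gate_set()))
  f2 <- fr$fraction[fr$gate == "R2"]
  se <- sqrt(0.3 * 0.7 / 40000)
  expect_lt(abs(f2 - 0.30), 3 * se)
})

test_that("damaged gate calibration places bounds at control quantiles", {
  ctrl <- event_table(data.frame(
    FL3 = withr::with_seed(11, rlnorm(10000, meanlog = 4.5 * log(10), sdlog = 0.15 * log(10)))))
  g <- calibrate_damaged_gate(ctrl, quantile_band = c(0.01, 1))
  expect_equal(g$name, "R3")
  expect_equal(g$bounds$FL3[["low"]], brute_quantile7(ctrl$FL3, 0.01))
  expect_equal(g$bounds$FL3[["high"]], Inf)

  # bounded upper quantile
  g2 <- calibrate_damaged_gate(ctrl, quantile_band = c(0.05, 0.95))
  expect_equal(g2$bounds$FL3[["high"]], brute_quantile7(ctrl$FL3, 0.95))

  # calibrated gate captures a heat-killed sample
  killed <- heat_killed_control(5000, seed = 2)
  gs <- gate_set(g, fsc_threshold = 0)
  lab <- assign_gates(killed, gs)
  expect_gt(mean(lab$label == "R3"), 0.95)
})

test_that("damaged-gate calibration rejects bad controls and bands", {
  flat <- event_table(data.frame(FL3 = rep(500, 200)))
  expect_error(calibrate_damaged_gate(flat, c(0, 1)),
               class = "flowseg_error_degenerate_control")
  few <- event_table(data.frame(FL3 = withr::with_seed(1, rlnorm(50, 10, 0.2))))
  expect_error(calibrate_damaged_gate(few),
               class = "flowseg_error_insufficient_control")
  ctrl <- event_table(data.frame(FL3 = withr::with_seed(2, rlnorm(200, 10, 0.2))))
  expect_error(calibrate_damaged_gate(ctrl, c(0.5, 0.4)),
               class = "flowseg_error_precondition")
})

test_that("gate and gate-set constructors enforce their invariants", {
  expect_error(gate("bad", FL3 = c(5, 5)), class = "flowseg_error_invalid_gate")
  expect_error(gate("", FL3 = c(0, 1)), class = "flowseg_error_invalid_gate")
  expect_error(
    gate_set(gate("A", FL3 = c(0, 1), priority = 1L),
             gate("A", FL3 = c(1, 2), priority = 2L)),
    class = "flowseg_error_invalid_gate")
  expect_error(
    gate_set(gate("A", FL3 = c(0, 1), priority = 1L),
             gate("B", FL3 = c(1, 2), priority = 1L)),
    class = "flowseg_error_invalid_gate")
  # log10 display-space bounds convert to linear on construction
  g <- gate("R3", FL3 = c(4, Inf), priority = 1L, space = "log10")
  expect_equal(g$bounds$FL3[["low"]], 1e4)
  expect_equal(g$bounds$FL3[["high"]], Inf)
})

test_that("gate sets round-trip through the YAML configuration format", {
  path <- system.file("extdata", "gates_synthetic.yaml", package = "flowseg")
  if (path == "") path <- file.path("..", "..", "inst", "extdata", "gates_synthetic.yaml")
  gs <- read_gate_set(path)
  expect_equal(gate_set_names <- vapply(gs$gates, `[[`, character(1), "name"),
               c("R1", "R2", "R3"))
  expect_equal(gs$fsc_threshold, 80000)
  expect_equal(gs$gates[[3]]$bounds$FL3[["high"]], Inf)
  # behaves identically to the in-code default
  tbl <- sample_events(culture_state(f_r1 = 0.5, f_r2 = 0.4, f_r3 = 0.1),
                       2000, seed = 17)
  expect_equal(assign_gates(tbl, gs)$label,
               assign_gates(tbl, default_gate_set())$label)
})
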