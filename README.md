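# flowseg

On-line flow cytometry turns a benchtop cytometer into a single-cell sensor
for bioreactors: every few minutes a sample is drawn, diluted in-line into
the instrument's linear range, stained with propidium iodide (PI), and
40,000 cells are recorded. The question the data must answer in real time
is *whether the population is segregating* — splitting into physiologically
distinct subpopulations (healthy PI-negative cells, intermediate-permeability
cells recruited under substrate limitation, and fully damaged cells) — and
by how much. `flowseg` implements this monitoring stack end to end in R:

* **I/O** — minimal FCS 3.0/3.1 list-mode files and the instrument CSV
  listmode dialect (`read_fcs()`, `read_listmode_csv()` and their writers);
* **gating** — rectangular R1/R2/R3 gates on the FL3 (PI) axis with the
  80,000 FSC acquisition threshold, plus calibration of the damaged-cell
  gate from a heat-killed control (`assign_gates()`,
  `calibrate_damaged_gate()`);
* **segregation statistics** — per-sample, per-channel, per-gate mean,
  median and the mean-to-median ratio

  MMR = mean(x) / median(x),

  which is ≈ 1 for a unimodal near-symmetric population and rises above 1
  when a minority subpopulation with higher signal appears; and the
  gate-based degree of segregation

  S = 1 − |f_R1 − f_R2|,  S ∈ [0, 1],

  0 when all cells sit in one gate, 1 when they are split half and half
  (`mmr()`, `degree_of_segregation()`, `summarize_sample()`);
* **a mechanistic simulator** — Monod batch/chemostat growth (μ =
  μ_max·S/(K_s+S)), a lumped ATP pool, a destabilized GFP reporter obeying
  dG/dt = α·μ² − (δ₀ + h(T)·δ_max·A/(K_A+A))·G − μ·G with a σ³²-like
  heat-shock induction h(T), limitation-driven recruitment of the
  intermediate subpopulation, and log-normal event sampling
  (`simulate_culture()`, `sample_events()`);
* **the sampling interface** — duty-cycle in-line dilution to ≤ 3·10⁶
  cells/mL, a ≥ 3 min PI stain hold, and Poisson event acquisition capped
  at 40,000 events per 60 s (`plan_cycle()`, `acquire()`);
* **an orchestrator** — multiplexed simulated experiments and off-line
  re-analysis of recorded files (`run_experiment()`, `analyze_samples()`),
  all tibble-in/tibble-out with `tidy()`, `glance()` and `autoplot()`
  methods.

## Worked example

Simulate the batch → chemostat → glucose-pulse experiment (3 h batch on
5 g/L glucose, then a chemostat at D = 0.14 h⁻¹, then 0.24 g glucose pulses
every 15 min), with a 40,000-event acquisition every 15 minutes:

```r
library(flowseg)
spec <- experiment_spec(scenario("chemostat_pulses"), seed = 1)
ex   <- run_experiment(spec)
ser  <- ex$series$R
ser
#> <segregation_series: 84 samples, t = 0.25..21 h, reactor R>

glance(ser)[c(4, 12, 48, 84),
            c("time", "frac_R1", "frac_R2", "degree_of_segregation",
              "mmr_FL3_overall")]
#>   time frac_R1 frac_R2 degree_of_segregation mmr_FL3_overall
#> 1    1   0.967   0.033                 0.066           1.523
#> 2    3   0.965   0.035                 0.070           1.545
#> 3   12   0.616   0.383                 0.767           4.505
#> 4   21   0.654   0.345                 0.691           4.442
```

During the batch phase almost every cell is healthy (R1 ≈ 97%, degree of
segregation ≈ 0.07). Once the chemostat imposes sustained glucose
limitation, cells are recruited into the intermediate-permeability R2 gate
(38% by 12 h), the degree of segregation climbs to ≈ 0.77, and the overall
FL3 MMR — which needs no gates at all — rises in parallel from 1.5 to 4.5.
The glucose pulses then partially relieve the limitation and both indicators
fall again. `autoplot(ser)` draws the three panels (gate fractions, degree
of segregation, MMR) over time.

The sampling interface does the arithmetic of the front end:

```r
residence_times(43, 0.14)
#> $volumes 6.02   $nearest 6      # 43 h of stabilization = 6 reactor volumes

plan_cycle(sampler_config(), 1e9)
#> <sampling_schedule: duty 0.003009, dilution 333.3x, contact 5 min, 3e+06 cells/mL>
#>   action         start_s stop_s
#> 1 fill-line            0     10
#> 2 co-pump/dilute      10     70
#> 3 stain-hold          70    250
#> 4 acquire            250    310
#> 5 flush              310    430
```

A 10⁹ cells/mL culture is brought exactly to the 3·10⁶ cells/mL linear-range
ceiling by running the sampling pump at a 0.3% duty cycle against the
continuous diluent flow, and the PI contact time (mixing + hold +
acquisition) is 5 min, above the 3-min minimum.

A thin CLI over the same functions ships in `inst/scripts/flowseg`
(`simulate`, `analyze`, `calibrate-r3` subcommands; all outputs CSV).

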