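---
title: "On-line monitoring of microbial population segregation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{On-line monitoring of microbial population segregation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowseg)
```

`flowseg` models an automated flow-cytometry loop on a bioreactor: a
peristaltic sampling pump feeds culture into a continuous diluent stream
carrying propidium iodide (PI), the diluted, stained sample runs through a
benchtop cytometer, and per-sample statistics are computed on the recorded
list-mode events. This vignette is the package's own account of the science:
the statistics it defines, the mechanistic simulator behind its synthetic
data, the tunable parameters and their defaults, and the numerical and
design choices a maintainer should know about.

## The segregation statistics

Two complementary indicators quantify population segregation per sample.

**Degree of segregation.** With `f_R1` the fraction of analysed cells in the
healthy (PI-negative) gate and `f_R2` the fraction in the
intermediate-permeability gate,

$$S = 1 - |f_{R1} - f_{R2}|, \qquad S \in [0, 1].$$

$S = 0$ when one gate holds everything, $S = 1$ at an equal split. The
inputs are **fractions**, not percentages: on a 0–100 scale the formula
leaves $[0,1]$, so `degree_of_segregation()` rejects inputs whose sum
exceeds 1 rather than silently rescaling. The statistic requires gating,
which is exactly its operational weakness on-line.

**Mean-to-median ratio (MMR).** For any channel's linear values,
$\mathrm{MMR} = \bar{x} / \tilde{x}$. A unimodal, near-symmetric population
has MMR ≈ 1; a minority subpopulation at higher signal drags the mean up
while the median stays with the majority, so MMR > 1 — and it grows both
with the minority's abundance (up to one half) and with the separation
between the modes. It therefore integrates the two ingredients of
segregation without any gates, which is what makes it usable for on-line
feedback. Statistics are computed on **linear raw channel values**: the
right-skew sensitivity that makes the MMR work lives on the linear scale. A
log-scale variant exists as the separately named `log_mmr()` and is never a
default. The median of an even-sized sample is the mid-average of the two
central order statistics, matching common instrument software.

Per-sample summaries (`summarize_sample()`) are computed on events above the
FSC acquisition threshold (default 80,000, inclusive `>=`), with no further
cleanup — where a protocol applies extra scrubbing before statistics, the
caller must do it explicitly. Gates holding fewer than 100 events get a
`low_count` flag: with a handful of cells the gate's mean and median lose
relevance (early cultures carry under 5% intermediate cells, and their
per-gate MMR is noisy for exactly this reason).

## Gating model

Gates are axis-aligned rectangles with **half-open, lower-inclusive**
intervals on linear channel values. The convention is deliberate: abutting
gates partition the axis, so every event gets exactly one label. Overlaps
are resolved by an explicit integer priority (largest wins) instead of being
forbidden — regions traced off a published dotplot may abut or overlap, and
a deterministic tie-break is testable. Gate configuration files may give
bounds in log10 display space; they are converted to linear on load so all
classification happens in one canonical space.

The damaged-cell gate R3 is anchored experimentally: cells inactivated at
65 °C for 30 min take up PI maximally, and `calibrate_damaged_gate()` places
the FL3 bounds at chosen empirical quantiles of such a control (default: 1st
percentile upward, unbounded above). The R1/R2/R3 coordinates shipped in
`default_gate_set()` and `inst/extdata/gates_synthetic.yaml` are **synthetic
placeholders** calibrated to this package's own generator — published
dotplots print no numeric boundaries, so real instruments need their own
gate file.

## The culture and reporter simulator

The synthetic-data generator is a lumped mechanistic model, first-class and
tested; its defaults define the simulated study conditions.

**Growth.** Monod kinetics, $\mu = \mu_{max}\, g(T)\, S/(K_s + S)$, with
batch ($\dot X = \mu X$, $\dot S = -\mu X / Y_{xs}$), chemostat (adds
$-DX$ and $D(S_{feed} - S)$) and pulsed-chemostat (instantaneous glucose
additions) phases. Defaults $\mu_{max} = 0.6\ \mathrm{h^{-1}}$,
$K_s = 0.05$ g/L, $Y_{xs} = 0.5$ g/g are conventional values for *E. coli*
on glucose minimal medium — modelling choices, not measurements from any
particular strain. $g(T)$ is a piecewise-linear factor anchored so growth at
30 °C is slowest and 42 °C fastest among the studied temperatures.
The biomass-to-event-density conversion uses $3.6\times10^{12}$ cells per
gram dry weight.

**ATP pool.** A lumped per-biomass scalar:
$\dot A = c\, q_s - (m + w\,(h(T)-1))\, A$ with $q_s = \mu / Y_{xs}$ —
source proportional to substrate uptake, first-order drains for maintenance
and for heat-shock protease work. No metabolic network is modelled; the
claims the simulator supports are at this lumped level.

**Reporter.** A destabilized GFP carrying an ATP-dependent degradation tag,
driven by a growth-responsive promoter whose synthesis flux follows the
square of the growth rate:

$$\dot G = \alpha \mu^2 s(T) - \left(\delta_0 + h(T)\,\delta_{max}
\frac{A}{K_A + A}\right) G - \mu G.$$

Defaults: $\alpha = 2000$ a.u.·h (free parameter — the literature gives the
$\mu^2$ rule but no constant; the default makes batch-phase G rise into the
hundreds of arbitrary units), $\delta_0 = 0.1$, $\delta_{max} = 0.9$
h⁻¹, $K_A = 0.2$ a.u. The ATP-replete degradation rate is therefore
$1.0\ \mathrm{h^{-1}}$, a half-life of 0.69 h — inside the sub-hour
half-life the destabilized variant is engineered for.

$h(T)$ is the σ³²-like induction factor: 1 at or below 37 °C; on an upshift
to 42 °C it starts at 17.5 (midpoint of the reported 15–20-fold spike) and
relaxes exponentially with a 5/180 h time constant — decayed over about
5 minutes — to 2.5 (midpoint of the reported 2–3-fold plateau). Midpoints
were chosen once and documented here.

$s(T)$ is a thermal efficiency on net synthesis (1 at ≤ 37 °C, 0.15 at
42 °C). It encodes an observation the $\mu^2$ rule alone cannot: at
heat-shock temperatures the reporter signal *falls* even though growth is
fastest. Mechanistically this bundles whatever reduces net accumulation at
42 °C beyond the modelled protease activity; it is a phenomenological
closure, not a claim about the promoter.

Two candidate mechanisms exist in the literature for reporter accumulation
under prolonged limitation — protein-leakage-driven promoter induction and
reduced ATP-dependent degradation. Only the degradation route is modelled
(the multiplexed evidence supports it directly); the leakage route is out of
scope, and simulated chemostat G therefore plateaus rather than slowly
rising over tens of hours.

**Subpopulation segregation.** The intermediate fraction relaxes first-order
(default time constant 1 h) toward
$f_{min} + (f_{max} - f_{min}) \cdot \ell$ where
$\ell = 1 - S/(S + K_s)$ is the limitation signal; defaults
$f_{min} = 0.03$ (unstressed cultures carry under 5% intermediate cells) and
$f_{max} = 0.5$ (the equal split at which $S$ reaches 1). The damaged
fraction changes **only** through an explicit `kill_culture()` event,
emulating the 65 °C control. Event sampling is multinomial membership plus
per-subpopulation log-normal FL3 (defaults: medians 150 / 2000 / $10^{4.5}$
a.u., log-sd 0.4 / 0.5 / 0.35), FL1 log-normal centred on current G
(widened from 0.35 to 0.6 log-sd after a heat shock, reproducing the
broadening of the GFP histogram when degradation sets in), and FSC/SSC
filler scatter placed almost entirely above the 80,000 threshold. Every draw
is a pure function of (state, n, seed).

**What the generator does *not* emulate.** Instrument noise floors,
spectral spillover and compensation, doublets and debris, carry-over between
samples, per-cell gene-expression stochasticity (distributions are
subpopulation-level), and the leakage-driven promoter route above. Passing
tests show the statistics and pipeline behave correctly on data with the
modelled structure; they do not validate the biology of any particular
strain or instrument.

## The sampling interface

In-line dilution is modelled as **duty-cycle modulation** of the sampling
pump: the sample pump (32 mL/min) injects culture a fraction $d$ of the
time into the continuous diluent flow (32 mL/min), giving delivered density
$\rho\, d Q_s / (d Q_s + Q_d)$. This is the package's interpretation of the
published two-pump sequencing — equal continuous co-pumping alone yields
only a fixed 2× dilution, which cannot reach the 3·10⁶ cells/mL linear
range from a dense culture; the physical tubing geometry that achieves more
is not printed anywhere, so the duty-cycle reading is flagged as an
interpretation, not a fact. Feasible duty cycles default to
$[10^{-4}, 1]$, letting the planner handle up to ~3·10¹⁰ cells/mL; beyond
that `plan_cycle()` errors and reports the pre-dilution factor required.

A cycle is fill-line (10 s), co-pump/dilute (60 s), stain-hold (the
configured 3-min minimum), acquire (60 s), flush (120 s) — 430 s, fitting
the 15-min period. PI (10 mg/L in the diluent) contacts the cells from the
mixer on, so the realized contact time is mixing + hold + acquisition =
5 min ≥ the 3-min minimum, enforced as a schedule constraint rather than
derived from tubing volumes (which are not available). The flush models the
line-cleaning step; carry-over itself is not simulated.

Acquisition is Poisson: arrivals at rate density × flow (33 µL/min) for up
to 60 s, truncated at the 40,000-event cap with the `truncated` flag set.
Off-line 30,000-event protocols need no special handling — they are just
another event table.

## Numerical choices

* **Integration** is fixed-step forward Euler with `dt <= 0.01` h. A step
  driving any state negative raises an error telling the caller to reduce
  `dt`; silent positivity clamping was rejected because it hides stiffness
  and corrupts mass balances. The shipped heat-shock scenario uses
  `dt = 0.002` h — a dense culture consuming a pulse makes the substrate
  balance stiff enough that 0.005 h overshoots.
* **Seeds.** All stochastic outputs are pure functions of (inputs, seed).
  Experiment-level seeds derive per-reactor seeds by a stable arithmetic
  hash of (global seed, reactor id), so a reactor's results are unchanged by
  adding or removing other reactors from a multiplexed run.
* **Ties and boundaries.** Gate intervals are half-open lower-inclusive; the
  FSC threshold is inclusive (`>=`); quantiles use R's default type-7
  interpolation; the even-`n` median is the central mid-average.
* **Degenerate inputs** error loudly with typed conditions
  (`flowseg_error_*`): empty samples, zero medians (off-scale samples),
  percent-scale segregation inputs, degenerate calibration controls,
  infeasible dilutions and schedules.

## Scenario time scales and problem sizes

The shipped `chemostat_pulses` scenario runs 3 h batch + 12 h chemostat +
6 h pulsing. The package's defaults compress the published-style 43 h
stabilization (6 residence times at D = 0.14 h⁻¹) so a full
simulate–sample–gate–summarize run (84 cycles × 40,000 events) completes in
well under a minute; the dynamics pass through the same regimes, only the
steady plateau is shorter, and full-length phases are available by passing
explicit phase times to `reactor_config()`. The heat-shock scenario starts
with a heavy inoculum (0.7 g/L) so the batch glucose is exhausted before the
4.5 h shock — the state the pulse experiments presuppose (the unpulsed
reactor must sit starved, with idle proteases). Acetate pulses are modelled
as glucose-equivalent substrate at a 0.4× energy yield: the model has one
substrate pool, and only the ATP consequence of the pulse matters for the
reporter.

## Known limitations

* The model family is deliberately lumped: one substrate, one ATP scalar,
  subpopulation-level distributions. It reproduces the monitored dynamics'
  shape, not strain-specific numbers.
* At 37 °C the $\mu^2$ synthesis rule makes simulated batch G higher than at
  30 °C; the ordering of absolute G between 30 and 37 °C is not constrained
  by the model and should not be read off the simulator.
* FCS support is minimal by design: list mode, integer/float data, both byte
  orders, no ANALYSIS segment, `$SPILLOVER` ignored with a warning. The CSV
  dialect is comma/point-decimal with a mandatory header; values are assumed
  linear-scale raw, and a log-exported file would need to be transformed
  before reading.
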