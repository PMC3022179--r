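---
title: "Analysing single-channel bilayer recordings with chankit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing single-channel bilayer recordings with chankit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chankit)
```

## The measurement and the model

In a planar lipid membrane (black lipid membrane) experiment a bilayer is
painted across a small aperture (here 300 µm) between two solution chambers,
a channel-forming peptide is added to the *cis* chamber, and the transmembrane
current is recorded under voltage clamp. The sign convention follows the
*trans* side: a negative applied voltage means the *trans* chamber is held
negative. Single channels appear as discrete square current steps; the
quantities of interest are

* the **central conductance** Λc: the centre of a Gaussian fitted to the
  probability histogram PΛ of per-event conductances Λ = |I/V|;
* the **opening frequency** in events per minute;
* the **open lifetime** distribution, summarised by the survival curve
  N(t) — the number of events that stay open at least *t* — fitted by
  N(t) = A₁·e^(−t/τ₁) + A₂·e^(−t/τ₂), where A₁, A₂ are zero-time amplitudes
  and τ₁ < τ₂ the fast and slow time constants (A₂ ≡ 0 gives the
  one-component model);
* the **ionic selectivity** P(K⁺)/P(Cl⁻), obtained by inverting the
  Goldman–Hodgkin–Katz (GHK) voltage relation at the measured reversal
  potential under a KCl gradient;
* the **tracer permeability coefficient** of the membrane (cm·s⁻¹) from a
  two-compartment radiolabel transfer experiment.

chankit implements this chain end to end, together with a stochastic gating
simulator that stands in for the recordings: original chart-paper data of
this kind are not machine-readable, so every statistical procedure here is
validated against synthetic recordings with known ground truth.

## The gating simulator

`gating_model()` describes a channel by an opening rate (Poisson intensity,
events/min, optionally voltage-indexed), an open-lifetime exponential
mixture (weight *w*, τ₁ ≤ τ₂), a Gaussian unit conductance (nS) drawn once
per opening (openings are square: within-event amplitude is constant), a
maximum stack of simultaneous open levels, baseline Gaussian noise (pA), and
optional burst ("paroxystic") episodes during which the opening rate is
multiplied by an intensity factor and events are flagged as uncountable.

Two deliberate semantics:

* **Arrivals are never discarded.** The ground-truth event table
  (`simulate_event_table()`) contains every Poisson arrival, so the event
  count over a recording is exactly Poisson — this is what frequency
  analysis estimates. `max_stack` caps only the *rendered* trace: an arrival
  while the stack is full is a real opening of a saturated pore and carries
  no extra current. With the default `max_stack = 1`, overlapping openings
  merge in the trace.
* **Closed times are exponential by construction.** Only open lifetimes are
  modelled from measured kinetics; nothing in the source data constrains
  closed-state structure, so arrivals are memoryless by decision, not by
  evidence.

Default parameters are the control condition of the study the package
models: 7.73 openings/min, a single open-lifetime component of 2.07 s, unit
conductance 0.161 nS, bath at 23 °C. The unit-conductance SD defaults to
0.02 nS (≈ 12 % CV): the published "± SE" on the central conductance is a
fitted-centre uncertainty, not a population SD, so the spread is a package
choice — and it must stay well below half the unit, or the "discrete square
events" the model emulates stop being resolvable into levels by any
threshold method (at 0.05 nS and +60 mV the level-1 and level-2 amplitude
bands overlap and idealization double-counts). Histogram-sampling checks of
the Gaussian fit use a wider 0.05 nS draw, which is a property of those
tests, not of the simulator. Baseline noise defaults to 0.5 pA, a typical
bilayer recording floor and ≤ 15 % of the ~9.7 pA unit amplitude at +60 mV.

What the simulator does **not** emulate: baseline drift, capacitance
transients, filter rise times, flicker/subconductance states, and missed-event
censoring by the recording bandwidth. Passing tests on this generator
therefore validate the estimators under clean square-event assumptions; they
do not certify performance on drifting or band-limited real traces.

## Idealization

`idealize_trace()` uses the half-amplitude threshold rule — the standard
idealization criterion when the original analysis was done by hand and the
criterion was never stated. With baseline *b* (trace median by default;
openings must be sparse for this to hold, otherwise pass a fixed baseline)
and unit amplitude *u*, the occupancy at a sample is
k = ⌊(I − b)/u + ½⌋, i.e. a level-k event starts when the current crosses
b + (k − ½)·u and ends on the reverse crossing. Stacked events are
decomposed into per-level occupancy segments; the reported amplitude of a
level-k event is its plateau mean minus baseline minus (k−1)·u, which keeps
one event ≈ one conductance unit in the histograms.

Numerical choices:

* **Dead time** (default 10 ms, the worst-case time resolution of a
  chart-recorder chain) is applied symmetrically: closures shorter than the
  dead time are bridged before openings shorter than the dead time are
  discarded. Without the bridging step a single noise sample below threshold
  would split long openings in two.
* **Auto unit amplitude**: samples more than 5 robust SDs above baseline are
  pooled; the unit is the first density mode carrying at least half the peak
  mass, sharpened to the median of the surrounding samples. Minor density
  bumps from threshold-transition samples must be ignored here, otherwise
  the level-2 threshold lands inside the level-1 amplitude distribution and
  events are double-counted.
* A flat trace with `unit_amplitude = "auto"` raises a no-unit-detectable
  error; non-uniform sampling is a format error.
* τ estimates are **not** corrected for missed events; durations below the
  dead time are simply absent.

`event_frequency()` divides the event count by the recording length in
minutes; with `exclude_bursts = TRUE` both the flagged events and the
burst-window time are removed, since openings cannot be counted during
paroxystic episodes. Each level onset counts as one event — how overlapping
openings were counted in the original tallies is unknowable, and this choice
is at least self-consistent between simulator and idealizer.

## Conductance histograms

`fit_conductance_histogram()` bins the conductances (Freedman–Diaconis by
default; the original bin widths were never stated, so the binning is always
reported with the fit), normalises to probabilities, and fits
a·exp(−(Λ−Λc)²/2σ²) by nonlinear least squares, mirroring the
histogram-plus-Gaussian workflow of graphing software used in the original
analyses. The reported uncertainty on Λc is the fit-parameter SE from the
least-squares covariance — whether the published "± SE" was this or the SEM
of raw conductances is not stated; the fit SE is used and said so. A
maximum-likelihood option (`method = "mle"`: mean, SD, SEM) is kept as a
cross-check and the two agree within 2·SE on unimodal data. Below 30 events
the fit refuses and `run_study()` falls back to the raw mean ± SD.
Multi-peaked histograms are out of scope: the modelled data are
single-peaked.

`compare_central_conductance()` is a Welch-style t-test on two fitted
centres using their SEs, with Welch–Satterthwaite degrees of freedom from
the event counts.

## Open lifetimes and model selection

`survival_curve()` evaluates N(t) at the sorted unique event durations —
no arbitrary grid, so N(0⁺) is exactly the event count. `fit_lifetime()`
minimises squared error of the one- or two-component model on these counts
with positivity bounds, using the Levenberg–Marquardt engine from minpack.lm
directly: on single-exponential data the two-component optimum is the
degenerate ray τ₁ = τ₂, where formula-interface fitters abort on a singular
gradient, while the raw optimizer converges and its SS is exactly what the
F-test needs. Initialisation takes τ₁ and τ₂ from the 25th and 75th duration
percentiles with the amplitude split evenly, plus a deterministic schedule of
rescaled restarts on non-convergence; order-2 results are canonically sorted
τ₁ < τ₂, so the fit is invariant to label permutation in the start values.

`select_lifetime_model()` applies the extra-sum-of-squares F-test,
F = ((SS₁−SS₂)/(df₁−df₂)) / (SS₂/df₂) with df = points − parameters,
selecting two components iff P < α (default 0.05; ties and a worse
two-component fit go to the simpler model, with F clipped at 0). Selections
with α ≤ P < 0.15 are additionally flagged *indeterminate* — published
open-time tables decline to choose in that region (e.g. a P of 0.102), and
the band, a package choice, simply reproduces that reporting habit without
overriding the α rule.

### A documented limitation: the F-test is strongly anticonservative here

Survival counts are cumulative, so their residuals are strongly positively
correlated, and SS₂/df₂ underestimates the noise scale relevant to the SS
difference. The acceptance suite measures the consequence: on pure
single-exponential data (300 events per replicate, 500 replicates,
α = 0.05) the two-component model is selected in roughly half the
replicates, not 5 %, and coarsening the survival grid does not repair it.
This is a property of the published procedure itself (least squares on
cumulative counts plus an F-test), which the package reproduces faithfully
rather than silently replaces; the corresponding acceptance test is
expected to fail and is kept as the record of the measurement. When
calibrated selection matters, fit the raw dwell times with
`fit_lifetime_mle()` (exponential MLE / EM mixture), which avoids cumulative
residuals entirely. Parameter *recovery* by the least-squares fit is
nonetheless accurate: with 2000 mixture draws the median fitted τ₁ and τ₂
land within 10 % and 15 % of truth, and the F-test's *power* against a
genuine two-component mixture exceeds 80 % — the miscalibration inflates
false positives, not the estimates.

## Selectivity (GHK)

For a K⁺/Cl⁻ system the GHK voltage relation is

V = (RT/F) · ln[(r·[K]ₜ + [Cl]꜀) / (r·[K]꜀ + [Cl]ₜ)],  r = P(K⁺)/P(Cl⁻),

with concentrations (not activities) and full KCl dissociation; at 23 °C
(the stated bath temperature), RT/F = 25.52 mV. `ghk_permeability_ratio()`
inverts this in closed form, r = ([Cl]꜀ − x·[Cl]ₜ)/(x·[K]꜀ − [K]ₜ) with
x = e^(VF/RT), valid strictly between the Cl⁻ and K⁺ Nernst limits; the
round trip is exact to 1e−12 relative error and r = 0 / r = ∞ recover the
Nernst potentials. Under 100/50 mM KCl the six published reversal potentials
invert to their published ratios within ±0.01 at two decimals (6.42 mV gives
0.454 → 0.45 against a printed 0.46 — one rounding step apart; the published
8.99 mV → 0.32 pair inverts to 0.31 at 23 °C and is treated as the source's
rounding, not a target). Reversal potentials come either from
`reversal_from_step_protocol()` (linear interpolation of the zero crossing
in a ±4 mV step sweep) or `fit_reversal_potential()` (OLS of I = g·(V−V_rev);
the slope is the channel conductance in nS).

## Tracer permeability

The source protocol names no formula, so `permeability_coefficient()` adopts
the standard initial-flux approximation for a single-timepoint two-compartment
design: P = J/(A·C_cis) with J the tracer appearance rate on the *trans*
side scaled from the sampled volume to the chamber. In counts the specific
activity cancels: P = (counts_trans/counts_cis) · V_chamber/(Δt·A), with
defaults V = 4000 µL, Δt = 30 min, A = π·(0.015 cm)² ≈ 7.07×10⁻⁴ cm². The
forward simulator (`simulate_flux_experiment()`) and this inversion
round-trip exactly in the noise-free regime. The published coefficients
(≈ 47×10⁻⁶ cm·s⁻¹) cannot be recomputed from the printed inputs and are not
reproduction targets; note that at plausible sampling activities the
expected trans-side counts under this formula are of order unity, so real
measurements must have integrated far more activity than the printed
protocol implies.

## The study driver, problem sizes, determinism

`run_study()` crosses conditions with voltages and, per cell: simulate →
idealize → conductance fit → frequency (bursts excluded) → order-1/order-2
lifetime fits → F-test, collecting tables plus a per-stage log; any cell
error is logged and the study continues. Every cell derives its own 32-bit
sub-seed from the config seed, so reports are bit-reproducible. The test
suite validates the estimators at deliberately modest problem sizes — e.g.
15-minute study recordings, 20 × 300 s idealization round trips, 500
replicate F-tests at 300 events, 2000-draw mixture fits over 20 seeds —
chosen as the smallest sizes at which the published effects (frequency
doubling, 0.161 vs 0.215 nS separation, τ recovery) are decisively
resolved.

Known limitations, beyond those noted above: no hidden-Markov/Viterbi
idealization and no kinetic state-network inference; no drift correction
beyond a constant baseline; no multi-Gaussian decomposition of multi-peaked
conductance histograms; no missed-event correction of τ estimates; no
isotope decay or unstirred-layer corrections in the flux module.
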