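---
title: "Modelling oxidative crystallin aggregation and its suppression by myo-inositol"
author: "crystagg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling oxidative crystallin aggregation and its suppression by myo-inositol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crystagg)
```

## The problem

Age-onset cataract is caused by light-scattering aggregation of lens
crystallins. Oxidation-mimicking variants of human γD-crystallin (such as
W42Q) are well folded at physiological pH and temperature, but rare
misfolded conformers can be kinetically trapped by a non-native internal
disulfide formed through exchange with oxidized glutathione (GSSG). These
disulfide-locked precursors aggregate through a bimolecular, dimer-forming
step into short extended chains that later collapse and coalesce into
globular particles. Solution turbidity, which is proportional to total
aggregated mass for these (non-amyloid) aggregates, is the experimental
observable. The lens metabolite *myo*-inositol — present at tens of
millimolar in the free water of the healthy lens nucleus and nearly absent
in cataractous lenses — suppresses this aggregation kinetically, without
binding the native state or changing the aggregates' morphology.

`crystagg` provides (i) a mass-action kinetic model of this redox-coupled
aggregation pathway with inositol acting on the bimolecular step, (ii) the
turbidity-trace statistics used to quantify aggregation kinetics (the
tangent method), (iii) power-law concentration-dependence and
dose-response analysis, (iv) glutathione redox arithmetic and PEGylation
gel-band simulation, (v) morphometry statistics for aggregate particle
tables, and (vi) a seeded synthetic plate-reader generator that stands in
for raw instrument data. The `analysis/` scripts in the source repository
run the full sequence of analyses over synthetic data.

## The kinetic model

Species (μM monomer equivalents unless noted): native monomer `N`,
misfolded reduced monomer `Ired`, disulfide-locked precursor `Iox`,
transient dimer `D`, extended-aggregate particle count `P0` (μM of
particles) and mass `P1`, suspended globule mass `G1`, settled globule
mass `S1`; glutathione `GSH`, `GSSG` and `inositol` in mM. Reactions:

* misfolding `N ⇌ Ired` (`k_mis`, `k_fold`);
* disulfide trapping `Ired + GSSG → Iox + 2 GSH` (`k_ox`), lumping the
  mixed-disulfide intermediate into one step that conserves
  `GSH + 2·GSSG`; reduction `Iox + 2 GSH → Ired + GSSG` with mass-action
  rate `k_red·[Iox][GSH]`;
* dimerization `2 Iox → D` at `k_dim · f` with the inositol inhibition
  factor `f = 1/(1 + [inositol]/K_I)`; dissociation `k_diss`; commitment
  of a dimer to a nascent chain (`k_nuc`; `P0 += 1`, `P1 += 2`);
* elongation `P + Iox` (`k_elong`, per particle), pairwise coalescence
  `2P → G` (`k_coal`, on particle numbers, mass-conserving), settling
  `G → S` (`k_settle`); settled material remains visible to the
  vertically-oriented optics;
* optionally (`dim_oxidizes`), a second route in which reduced misfolded
  monomers dimerize first and the dimer is oxidized by GSSG — the two
  orderings of misfolding and oxidation are not mutually exclusive.

Turbidity is `τ = w_P·P1 + w_G·(G1 + S1)`. With `w_G = w_P` turbidity is
strictly proportional to aggregated mass; the shipped default
`w_G = 2·w_P` gives coalescence a larger optical weight, which is what
permits biphasic traces. The tension between strict mass-proportionality
and coalescence-driven second phases is real in the data this model
emulates and is deliberately exposed as this single weight ratio.

Monomer equivalents and `GSH + 2·GSSG` are conserved exactly by the rate
equations; trajectories are integrated with a stiff solver (`deSolve`,
lsoda, absolute tolerance 1e-12 μM, relative 1e-8) on a 90 s output grid
(the plate-reader read interval), and conservation is re-checked on every
trajectory to 1e-6 relative. Zero protein gives a flat zero trace rather
than an error.

Two moments (`P0`, `P1`) represent the extended aggregates instead of a
full length distribution; mean chain length is `P1/P0` (≈ 5–7 under the
defaults, matching the short-chain morphology). Because there is no
globule-count moment, only the pairwise `2P → G` coalescence channel is
implemented; capture of chains by pre-existing globules is absorbed into
the same rate constant.

## Why inositol suppresses more strongly in redox buffers

The inhibition factor acts only on dimerization, yet the observed
rate suppression is larger in glutathione redox buffers (OxD 0.15–0.40)
than under full oxidation. In the model this synergy is emergent, not
fitted shape-by-shape: in a redox buffer the precursor pool `Iox` is held
near its thiol–disulfide quasi-equilibrium with the large native
reservoir, so the aggregation flux is proportional to `f·k_dim·Iox²` with
`Iox` essentially unchanged by the inhibitor — suppression approaches
`1 − f`. Under full oxidation there is no reduction channel; `Iox` is a
depleting stock, and blocking dimerization lets it accumulate, partially
compensating the inhibition. The distance from quasi-equilibrium at the
time of maximum rate is controlled by `k_dim`, which is why the pair
(`K_I`, `k_dim`) suffices to calibrate both printed suppression
percentages (35% fully oxidizing, 51% redox-buffer mean).

## Default parameters and calibration

The defaults ship in `inst/extdata/default_params.json`. All rates were
fixed once at round values chosen for trace shape — sigmoidal growth over
a 4.5 h assay, short chains, near-quadratic concentration dependence —
and only `K_I` and `k_dim` were calibrated, by least squares on the two
printed suppression percentages (see `scripts/calibrate.R`):

| parameter | value | units | role |
|---|---|---|---|
| `k_mis` / `k_fold` | 8e-4 / 4e-3 | 1/s | misfolding equilibrium (~17% misfolded) |
| `k_ox` / `k_red` | 1.0 / 0.1 | 1/(mM·s) | glutathione exchange |
| `k_dim` | 5.09e-7 (calibrated) | 1/(μM·s) | rate-limiting bimolecular step |
| `k_diss` / `k_nuc` | 5e-4 / 5e-3 | 1/s | dimer fate |
| `k_elong` | 2e-4 | 1/(μM·s) | chain growth (short chains) |
| `k_coal` / `k_settle` | 1e-3 / 2e-4 | 1/(μM·s), 1/s | coalescence, settling |
| `K_I` | 45.4 (calibrated) | mM | inositol inhibition constant |
| `w_P` / `w_G` | 0.02 / 0.04 | AU/μM | turbidity weights |

`K_I` here is a microscopic constant of the dimerization step; the
*macroscopic* half-suppression concentration of the measured maximum rate
is considerably larger (fitting the simulated dose-response gives an
effective value of roughly 260 mM) because of the compensation described
above. Neither value is a measured quantity from the underlying study,
which reports no rate constants; the parameter set is a minimal scheme
reproducing the qualitative claims plus the two calibration percentages.

## Trace statistics: the tangent method

`tangent_fit()` implements the tangent method: the slope of the best-fit
tangent to the steepest part of a turbidity trace is the maximum
aggregation rate; the x-intercept of that tangent against the baseline
(mean of the first three readings by default; the baseline definition is
configurable since the source assays normalize but never define one) is
the apparent lag time. Negative lags are reported as-is with a warning
flag.

The steepest point is located on a Savitzky–Golay (local quadratic)
smoothed derivative. When that derivative shows a clear interior peak,
the estimate is refined by fitting a four-parameter logistic to the phase
and using its analytic inflection tangent (`max rate = Lk/4` at `t0`,
lag `t0 − 2/k` for zero baseline): on sigmoidal traces this removes the
read-interval discretization error entirely (exact to well under 0.5%
even for transitions only a few reads wide). On non-sigmoidal traces
(ramps), or when the logistic explains less than 98% of the phase
variance, the discrete tangent anchored at the steepest sample is used.
The estimator is scale- and time-shift-equivariant.

Biphasic traces are segmented by `segment_phases()`: phases are intervals
around local maxima of the derivative that exceed 10% of the global
maximum and are separated by a valley below 50% of the smaller adjacent
peak. Two robustness rules matter on noisy data: segmentation uses a
derivative smoothed at a coarser scale (about an eighth of the trace
length — growth phases in these assays last hours), and a phase must
contribute at least 10% of the total turbidity rise; without these, 2%
reader noise reliably splits the single main rise of every simulated
well into spurious "phases". The `"second_phase"` rule computes the
kinetic statistics from the second phase when a trace is biphasic and
falls back to the only phase otherwise, matching how biphasic assays are
analysed case by case.

`dose_response()` normalizes maximum rates to the zero-dose rate and
optionally fits `rate = R0/(1 + d/K_I)`. The scale `R0` is estimated
jointly on the raw rates rather than dividing all observations by a
single noisy zero-dose reading: normalization first would correlate every
residual with the zero-dose error and understate the `K_I` standard
error (in coverage simulations the literal normalized one-parameter fit
covers the truth at 2 SE in only ~50% of seeds; the joint fit is
correctly calibrated).

## Synthetic data generator

`make_plate()` drives the kinetic model for each well of a design and
applies the noise model: multiplicative lognormal noise with unit mean
(σ = 2% by default — plate-reader turbidity noise scales with signal)
plus one additive baseline offset per well from Normal(0, 0.005 AU).
Every well–replicate derives an independent substream from the design
seed, so output is bit-reproducible and independent of well order.
Late-addition protocols (`late_addition_plate()`) integrate up to the
event, apply dilution/mixing exactly at the event time, drop one read of
instrument dead time and flag the next reading. Temperature is carried
as metadata only (no Arrhenius scaling). `synth_morphometry()` emulates
manually traced TEM particle tables: Poisson per-image counts, lognormal
sizes, two morphology classes, with treatment effects on size scale,
distribution shape and counts.

What the generator does *not* emulate: pipetting/edge effects, drift,
evaporation, optical saturation at high turbidity, correlated noise
between neighbouring reads, or real TEM segmentation ambiguity. Tests
passing on synthetic plates therefore validate the statistical machinery
and the model's internal consistency, not instrument-specific artefact
handling.

## Numerical choices and degenerate inputs

Integrator tolerances as above; concentrations more negative than −1e-9
abort the run, smaller negative round-off is zeroed. Savitzky–Golay
endpoint handling reproduces polynomials exactly at the boundaries, so
quadratics pass through `smooth_trace()` unchanged. The logistic
refinement is initialized from the discrete estimate and bounded
(`L, k ≥ 0`); ties in rank-size ordering keep input order; the exact
two-sample KS p-value is used when `n·m ≤ 10⁴`, the asymptotic form
otherwise; the default two-sample t test is the Student pooled-variance
form, with Welch behind a flag.

## Known limitations

* The per-lane *fractions* of the simulated PEGylation gel do not
  reproduce the intensification of the fully reduced band under
  inositol; the *absolute* band intensity does (more protein remains
  soluble and reduced). In the model the control's soluble pool is
  slightly more reduced fractionally because aggregation sequesters
  oxidizing equivalents — the observable that matches the gel data is
  intensity at equal loaded volume, which is what `pegylation_lane()`
  exposes through its `load` argument.
* Late-addition suppression is dose-dependent but weaker than the
  underlying study's traces suggest: pre-existing chains keep elongating
  and coalescing regardless of the inhibitor, and only new-particle
  formation is blocked. A model in which suspended globules capture
  chains (a globule-count moment) might sharpen this.
* Default-parameter traces are monophasic; clearly biphasic traces arise
  in this model only under late-addition disruption, not spontaneously
  at low OxD as in the source data. The two-moment closure smooths the
  coalescence second phase into a shoulder.
* The exponent increase with inositol in the concentration-dependence
  analysis emerges here (≈ +0.3) without an explicit trimer-nucleation
  channel; whether such a channel is required in reality is left open.

## Problem sizes

The shipped analyses use 4.5 h assays at 90 s reads (181 points per
trace), plates of 24–36 wells, dilution series of four concentrations,
and coverage simulations of 100 seeds with quadruplicate 6-point dose
series — sizes at which every analysis in `analysis/` and the full test
suite complete in well under a minute on a laptop.
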