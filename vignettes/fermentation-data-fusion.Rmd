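---
title: "Fusing multi-rate fermentation data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing multi-rate fermentation data: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermfuse)
```

## The problem

A fermentation experiment produces three classes of measurements that
never share a clock. Online bioreactor sensors (pH, dissolved oxygen,
temperature, agitation, air flow, broth weight, pump rates) log on a
dense, regular grid — here about once per minute. At-line instruments,
typified by an off-gas mass spectrometer multiplexed over several
reactors, deliver one composition reading per channel per instrument
cycle, roughly every 20 minutes. Offline assays — biomass OD600, product
titer — arrive every 2–4 hours at irregular times. Almost everything one
wants to know about the culture (respiration rates, specific rates,
yields, a real-time biomass estimate) requires these streams on a single
time axis. `fermfuse` implements that fusion step and the analytics that
sit on top of it, with a synthetic fed-batch generator as a fully
controlled test bed.

## The fusion procedure

The online grid is the reference: it is the densest stream and the one
process control acts on, so all other streams are brought to it and the
online time points are preserved exactly. Per source class:

1. **At-line series** are *section-averaged*: all readings inside one
   instrument cycle (default 20 min) are replaced by their mean, stamped
   at the cycle midpoint. Gaps inside a series may first be repaired by
   averaging the adjacent readings.
2. **Section means are interpolated** onto the online grid by two-point
   (degree-1) Lagrange interpolation, i.e. piecewise-linear
   interpolation between bracketing observations. Higher-degree Lagrange
   polynomials are deliberately not offered: on 20-minute-to-hours gaps
   they oscillate, and exactness at the knots plus exactness on affine
   signals is what the downstream balances actually need.
3. **Offline series** are first *anchored* — each observation snapped to
   the nearest grid time (ties resolved toward the earlier observation,
   so no value is ever attributed to the future) — then linearly
   interpolated between anchors.

Outside a sparse stream's observed span the default policy is
*hold-nearest*, flagged in the per-column provenance; an `error` mode is
available when silent extrapolation is unacceptable. Nearest-time
alignment (no interpolation at all) can be selected per variable for
inherently step-like channels.

Two properties pin the implementation down and are enforced by tests:
fusing any affine signal reproduces it at every grid point to 1e-12, and
nearest-alignment output values are always a subset of the input values.
Fusion is idempotent — re-fusing an already-fused frame is the identity.

### Choices the data did not make for us

* *Cycle-midpoint stamping.* A section mean could be stamped at the
  cycle start, end, or midpoint. We use the midpoint (configurable): it
  is the unbiased choice for a mean over the cycle, and an instrument
  that sweeps its channels near-uniformly realises it almost exactly.
* *Batch start time.* All times are decimal hours since inoculation.
  Source tables using wall-clock timestamps are converted at load; the
  inoculation time must then be present in the batch metadata rather
  than inferred from the first sample, because the first logged sample
  routinely predates inoculation.
* *Missing values* are an explicit sentinel (empty cell = not observed,
  literal `NA` = observed-but-missing), never silently dropped, so every
  fill operation is auditable after the fact.

## Derived physiology

With compositions in percent, inlet flow $F$ (ml/min) and broth mass $m$
(kg), the inert-gas (N₂) balance gives

$$\mathrm{CER} = \frac{F}{m}\left(\frac{y_{N_2,in}\,y_{CO_2,out}}{y_{N_2,out}}
 - y_{CO_2,in}\right)\frac{1}{100}\cdot\frac{60}{22.4}, \qquad
\mathrm{OUR} = \frac{F}{m}\left(y_{O_2,in} -
 \frac{y_{N_2,in}\,y_{O_2,out}}{y_{N_2,out}}\right)\frac{1}{100}\cdot\frac{60}{22.4},$$

in mmol·kg⁻¹·h⁻¹, and $\mathrm{RQ} = \mathrm{CER}/\mathrm{OUR}$. Two
unit conventions deserve a note. First, the percent-to-fraction
conversion must be applied exactly once; `gas_rates()` keys it off a
single `percent` flag, and dimensional analysis (22.4 L/mol at standard
conditions; ml·min⁻¹ to mmol·h⁻¹) fixes where it belongs. Second, the
molar volume is used as 22.4 L/mol without temperature correction — a
deliberate simplification, adequate for trend-level physiology and
stated here so nobody mistakes the output for a reconciled carbon
balance. RQ is undefined wherever OUR is zero; since fused frames admit
no missing values, the RQ column is omitted (with a warning) in that
case rather than carrying a sentinel.

Offline-anchored rates come from the component balance
$dM/dt = F_{in}c_{in} - F_{out}c_{out} + R + T$: the process rate $R$
(amount/h), the reactor rate $r = R/m_{avg}$, and the cell-specific rate
$q = R/(OD\cdot m)_{avg}$, with yields $Y_{i/j} = R_i/R_j = r_i/r_j =
q_i/q_j$. The level-invariance of $Y$ holds exactly when both rates
share the same averaging denominators, and `yield_coefficient()` asserts
it to 1e-9 relative tolerance as a cheap consistency check on caller
bookkeeping. $dM/dt$ is estimated by central differences (one-sided at
the ends, exact on affine signals); the transfer term $T$ defaults to
zero because it is rarely instrumented. The averaging window for
$m_{avg}$ and $(OD\cdot m)_{avg}$ follows the differencing window.

## Device-fault rules

The fault module is generic over any monitored signal; its defaults are
the ambient-CO₂ self-check of an off-gas spectrometer, which
periodically samples outside air: a rolling mean outside 0.02–0.05 % or a rolling
coefficient of variation above 0.1 marks the instrument as needing
correction. Numerical choices: the CV uses the sample (n−1) standard
deviation; windows are centred and time-based (default 1 h) so they
survive irregular cadences; anomalous runs separated by up to one window
are merged; excursions shorter than one window are reported but tagged
`transient`; zero-mean windows make the CV undefined and are tagged
`indeterminate` without contributing to the verdict. The mean-band rule
is intentionally *not* scale-free while the CV rule is — rescaling a
signal moves it through an absolute band but leaves sd/mean untouched —
and the tests pin both behaviours. A rolling evaluation was chosen over
per-calibration-episode means because it needs no episode bookkeeping;
an episode mode can be emulated by setting the window to the episode
length.

## Multi-batch analytics

Both PCA procedures start from batches resampled onto a shared grid
(intersection of spans, capped at 2000 points) and z-scored per column;
process variables span incommensurate units (rpm next to pH), so
unscaled PCA would be an exercise in unit choice. Component signs are
fixed by making each loading's largest-magnitude entry positive, purely
for reproducibility.

* The **flat view** turns each batch into one row (all variables at all
  grid times); batches become points in (PC1, PC2) and deviant batches
  separate from the cluster.
* The **time view** stacks (batch, time) rows over variables; PC1/PC2
  become per-batch trajectories, smoothed with a Savitzky–Golay filter
  (default window 11 points, order 3 — wide enough to suppress sensor
  noise, narrow enough to keep a 1–2 h disturbance visible; SG is exact
  on polynomials up to the filter order, so smooth trajectories pass
  through unchanged). Smoothing is applied *after* the reduction: the
  reduction is linear, so filtering before or after differs only at the
  trajectory ends, and smoothing last keeps the scores interpretable as
  filtered projections of the raw data.

`locate_disturbance()` operationalises "find the peak and read the
loadings": it subtracts the across-batch median trajectory, removes the
smooth between-batch divergence with a wide SG baseline (default 51
points), takes the component and time of the largest residual excursion,
and returns the variables ranked by absolute loading on that component.
A disturbance confined to one variable carries most of its variance on a
minor component; searching the top three components rather than PC1
alone is what makes the attribution land on the right variable.

The Spearman screen pools paired observations and reports rank
correlations (average ranks on ties) with two-sided p-values — exact by
permutation for n ≤ 10 without ties, the large-sample t approximation
otherwise. No multiple-testing correction is applied by default, since
the screen is exploratory; Benjamini–Hochberg is one flag away.

## Soft sensing

`assemble_samples()` turns every fused grid point with a target value
into one training sample; spans flagged by a fault report can be
excluded, mirroring the manual removal of process anomalies before
training. The split is an exact 8:2 partition (sizes `round(0.8 n)` /
`round(0.2 n)`, deterministic per seed), random over pooled samples by
default to match common practice; a batch-blocked mode exists and is the
methodologically safer choice when batches are few, because neighbouring
time points are strongly dependent and a pooled split flatters
validation error.

The regressor is a contract — `fit`, `predict`, plain-list
serialization — with two implementations: a linear least-squares
baseline (used in tests where the target is realizable, so any defect
shows up as a nonzero residual) and a feed-forward MLP (tanh hidden
units, linear output, full-batch Adam, default six layers: input, four
hidden of widths 32-16-8-4, output). Features are z-scored with
training-set statistics only, and those statistics travel inside the
model, so streaming prediction is self-contained and stateless per grid
point. The target is standardized internally and restored at
prediction, making the default learning rate scale-free.

## The synthetic generator

The generator emulates what the pipeline assumes about real streams:
three cadences (1 min online, 20 min at-line cycles stamped at
midpoints, offline gaps drawn uniformly from 2–4 h), per-variable
Gaussian noise, and injectable sensor faults (step, drift,
variance-burst). Its defaults describe a 72 h fed-batch: logistic growth
to carrying capacity 40 OD with μ_max 0.25 h⁻¹; a genuinely flat lag
phase of 10 h implemented as a smooth logistic ramp of the specific
growth rate (time constant 1.5 h) with a closed-form biomass solution;
oxygen demand as a growth-linked term (15 mmol O₂ per OD per kg) plus
maintenance (0.6 mmol O₂ per OD per kg per h); a constant respiratory
quotient of 1.05; dry-air inlet (20.96 / 0.04 / 79.00 % O₂/CO₂/N₂) at
1000 ml/min into 0.8 kg of broth fed at 5 g/h from 8 h. The flat lag is
not cosmetic: the first half at-line cycle is covered by hold
extrapolation, and only a culture whose respiration is genuinely static
there keeps the round-trip error within the interpolation budget — which
is also true of real lag-phase cultures.

Outlet gas fractions are obtained by *inverting* the off-gas balance
from the target CER/OUR, with N₂ closing the composition to 100 %. This
makes the generator and `gas_rates()` exact inverses by construction, so
the noiseless fuse-and-derive round trip isolates interpolation error
alone — the package's strongest end-to-end check (≤ 0.5 % relative at
every grid point at default cadences, enforced in the acceptance tests).

What the generator does *not* emulate, and what passing tests therefore
do not show: substrate and by-product kinetics (no ODEs beyond
logistic growth), gas-phase holdup and sensor response dynamics
(mixing is instantaneous), pressure/humidity effects on the off-gas
balance, OD-versus-viability divergence late in fermentation (real
OD600 overestimates living biomass as cells die, which is exactly where
real soft sensors degrade), and correlated or heavy-tailed sensor noise.
Results on simulated data bound the method's numerical behaviour, not
its biological fidelity.

Problem sizes used in the tests and the acceptance script — 6–24 h
batches for unit-level checks, the full 72 h default for the round trip,
50 seeded simulations for the fault study, n = 2000 samples for the
soft-sensor recovery — were chosen as the smallest sizes at which each
property is meaningfully exercised.

## Known limitations

* One-process batch semantics: re-running over a growing batch
  directory is idempotent, but there is no incremental/streaming fusion
  with backfill on late-arriving data.
* Export is CSV (full precision, bitwise round trip); no spreadsheet
  writer is bundled.
* The register codec handles the scaled-integer payload only; live
  fieldbus transports are out of scope.
* The fault module detects; it does not correct or recalibrate.
* Percent-unit gas compositions are assumed unless `percent = FALSE`;
  mixed-unit inputs are the caller's responsibility.
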