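---
title: "Trial-based hemolysis modelling for continuous-flow LVADs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial-based hemolysis modelling for continuous-flow LVADs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemolag)
```

## The problem

Continuous-flow left ventricular assist devices (LVADs) shear red blood
cells.  The released plasma-free hemoglobin (pfHb) is both a clinical risk
marker and a design constraint, and the question this package answers is:
*how much hemolysis does a given operating mode produce, for a given
patient state, without running computational fluid dynamics?*  The answer
is built from in vitro hemolysis trials of the physical pump, which makes
the whole chain cheap enough to sweep hundreds of operating modes.

The package models the Sputnik1 axial-flow pump by default (all defaults
are its identified parameters), but every building block is
re-parameterizable for other continuous-flow pumps.

## Model chain

Four submodels advance together at one global step $\Delta t$ (default
0.0004 s):

1. **Speed loop** — the closed-loop dynamics from reference speed
   $n_{ref}$ to actual speed $n$ are a unity-gain second-order lag with
   dead time, $1/(k_2 s^2 + k_1 s + 1)\,e^{-T_d s}$.  The default
   coefficients give a damping ratio of about 1.18 (no overshoot).  The
   recurrence is the exact zero-order-hold discretization, with the dead
   time as a ring buffer of $\mathrm{round}(T_d/\Delta t)$ reference
   samples, so the discrete response is exact at the sample times rather
   than a step-size-dependent approximation.
2. **Hydraulics** — pump flow $Q$ (L/min) obeys
   $L\,\dot Q = aQ + bn^2 + cQ^x n^y - \Delta P$, the head pressure
   $\Delta P$ being aortic minus left-ventricular pressure.  Explicit
   Euler at the global step is used: the inertance $L$ is small
   (0.74 mmHg·s·min/L) so the stiffness is mild, and the tests compare
   the Euler path against a high-accuracy `deSolve` integration
   (< 0.1 % of flow over 10 s).
3. **Cardiovascular system** — an eight-compartment lumped-parameter
   circulation (see below) returns $p_{ao}$ and $p_{lv}$ given the LVAD
   flow, which is drawn from the left ventricle and returned to the
   aorta.
4. **Hemolysis** — the trial-identified power law made dynamic by a
   Lagrangian particle scheme (see below).

## The static power law and its exposure-time form

The hemolysis rate index (HRI, %·mL/h) is the hourly rise of pfHb
normalized to total hemoglobin, hematocrit and loop volume; one in vitro
trial at constant speed and flow yields one HRI.  The static model is

$$\frac{HRI}{\overline{HRI}} = c_2
  \left(\frac{Q}{\overline{Q}}\right)^{a_2}
  \left(\frac{n}{\overline{n}}\right)^{b_2},$$

with scaling constants $\overline{HRI} = 43.22$, $\overline{Q} = 4.65$
L/min, $\overline{n} = 7415$ rpm and fitted exponents $c_2 = 0.740$,
$a_2 = -0.394$, $b_2 = 5.45$ for the default pump.  The signs matter:
hemolysis falls with flow (shorter exposure) and rises steeply with speed
(higher shear).  The package treats all HRI values in %·mL/h.

Substituting the exposure time $t_{exp} = V_i/Q$ of the impeller region
(volume $V_i$ = 7.04 mL, path length $l_i$ = 55 mm) turns the flow
dependence into a time dependence,
$HRI = \hat c_2\, t_{exp}^{\hat a_2}\, n^{b_2}$ with $\hat a_2 = -a_2$.
Inside this reduction flows are in mL/s so that $V_i/Q$ is a time in
seconds; the conversion lives at the module boundary
(`reduce_params()`), and a property test checks the reduced form equals
the static law to machine precision.

## The Lagrangian particle scheme

At every step one particle enters the impeller region at $l = 0$; each
particle advances by $\Delta l = Q\,l_i/V_i\,\Delta t$ and accumulates
damage through the effective-time rule: the exposure time that would
explain the particle's current damage *at the current speed* is
recovered, incremented by $\Delta t$, and re-evaluated.  This makes the
accumulation history-consistent under time-varying speed, and at constant
speed it collapses exactly to elapsed time — a particle that sees a flow
step mid-impeller exits with the same damage as one that saw the mean
residence time, which the tests verify against a closed-form segment
composition.

Particles with $l \ge l_i$ are removed after the update in which they
cross the boundary; their final value is the exit damage.  The reported
HRI is $f$ times the mean over all particles currently in the region.
The mean is taken *after* removal and injection, so a region at flow $Q$
holds $\lceil V_i/(Q\Delta t)\rceil - 1$ particles at steady state
(about 2112 at 0.5 L/min, 87 at 12 L/min).

**Correction factor.** Averaging over the region underestimates the exit
value because damage grows sublinearly with residence time
($\hat a_2 \approx 0.394 < 1$): with uniformly distributed particle ages
the mean is the exit value divided by $1 + \hat a_2$.  The factor $f$ is
therefore calibrated as the ratio of the direct power-law HRI to the
uncorrected Lagrangian aggregate at a constant 0.5 L/min; the speed
cancels algebraically in this ratio (verified to 1e-9), and the discrete
calibration at $\Delta t$ = 0.0004 s gives $f \approx 1.393$ against the
continuous-limit value $1 + \hat a_2 = 1.394$.  Calibrated at one flow,
the corrected aggregate then matches the direct law within 0.7 % over
the whole 0.5–12 L/min, 6000–9000 rpm grid — the residual error is the
flow-dependent discreteness of the age distribution ($N$ varies by a
factor 24 across the grid).

The scheme is flagged transient until the first injected particle has
exited (one washout): before that the region average is biased low by
construction, so per-cycle metrics discard it.

Backflow ($Q \le 0$) is outside the model's validity and aborts the
simulation; the trial campaign it is built on could not realise flows
below 0.5 L/min.

## Trial analysis and fitting

`hri_intervals()` evaluates the per-interval HRI from hourly blood
samples, using the interval-*start* volume, hematocrit and hemoglobin
(the definition does not pin the endpoint; the start convention is
declared and tested), and pfHb/Hb are put on a common mg/dL scale before
the ratio.  Negative pfHb increments are kept (assay noise) but flagged.
A trial's HRI is the mean of its six hourly intervals.

Because nominally identical pump builds hemolyse at different absolute
levels, per-device HRIs are standardized (divided by the device mean,
multiplied by the common $\overline{HRI}$) before pooling; a test checks
that devices with proportional patterns collapse onto identical values.

`fit_power_law()` fits on the linear (untransformed) scale by iteratively
reweighted nonlinear least squares with Tukey bisquare weights (tuning
constant 4.685, at most 50 reweighting rounds), started from a log-log
ordinary regression.  Fitting on the linear scale weights the large-HRI
(low-flow, high-speed) corner appropriately; the log-log start makes the
nonlinear iteration reliable.  RMSE and $R^2$ are reported with unit
weights on the standardized data, since the weighting convention behind
the published statistics is not documented.

## The cardiovascular model

The circulation is eight compliance compartments — left/right ventricle,
left/right atrium, systemic arterial/venous, pulmonary arterial/venous —
joined by resistances and ideal diode valves with small series
resistances (no regurgitation).  Ventricles follow a double-Hill
time-varying elastance between end-diastolic and end-systolic values;
`cf_lv` scales the left-ventricular end-systolic elastance (0.25 at the
heart-failure baseline), `f_rsys` scales the systemic resistance, and
heart rate sets the cycle length with a fixed systolic fraction.  Atria
are passive compliances (no atrial kick) and ventricular interdependence
is a small linear septal pressure coupling — the interaction mechanism
is named by the source topology but not quantified there, so a
configurable coefficient (default 0.02) was chosen.

The parameter values themselves are this package's own: the literature
model the topology follows is not published with numbers.  They were
tuned once so that the *unsupported* baseline reproduces textbook
decompensated heart failure (about 70/49 mmHg aortic pressure, cardiac
output ≈ 3 L/min at HR 75, `cf_lv` 0.25), and all quantitative claims
about the coupled system are therefore trend-based: with support, mean
flow and mean HRI rise with speed, pulse pressure falls, higher
afterload lowers flow and raises HRI, heart rate barely moves HRI.
Absolute coupled numbers (e.g. the exact percentage HRI change of a
given modulation profile) depend on this parameterization and should be
read as illustrative, not as device predictions.

Integration is explicit Euler at the global step; volume is conserved to
floating-point accuracy by construction (every flow leaves one
compartment and enters another), and a test bounds the drift below
0.1 % per simulated minute.  A negative compartment volume aborts with
an error rather than being clamped.

## Speed-modulation profiles

Cardiac-cycle-synchronised rectangular profiles are anchored to their
mean: the high level is $\bar n + (1-d)\,A$ and the low level
$\bar n - d\,A$ for duty $d$ and peak-to-peak amplitude $A$, so the
unfiltered time average equals the mean speed exactly for every duty —
sweeps over duty stay comparable at fixed mean.  (Whether the physical
controller splits the amplitude symmetrically is unknown; this
construction is declared instead.)  A causal one-pole low-pass (20, 5 or
2 Hz) shapes the wave and is warm-started over repeated cycles until
periodic, so the emitted cycle is the periodic response; the phase shift
is a circular rotation applied afterwards.  Feasibility (6000–9000 rpm)
is checked on the unfiltered levels, which bound the filtered ones.

The sweep enumerator builds the cartesian grid of means {6500, 7500,
8500} rpm, amplitudes 500–3000 rpm, the three cutoffs and 5 % duty/phase
grids, dropping infeasible combinations.

## Simulation protocol and problem sizes

Coupled runs discard max(one washout, 10 cardiac cycles) as transient
and analyse the following complete cycles; the default 16-cycle run
leaves five to six analysis cycles, over which the cycle-to-cycle mean
HRI varies by less than 0.1 %.  Cardiac output under support is defined
as the cycle average of total forward aortic flow (aortic valve plus
LVAD) — the clinical quantity is not uniquely defined under assist, so
the definition is stated.  The physical simulation is deterministic;
seeds affect only the synthetic-data generators.

The package's own verification runs use: the full 7 × 24 equivalence
grid for the Lagrangian-vs-direct comparison; a 31-point constant-speed
sweep (100 rpm steps); and the modulation sweep on a reduced 3 × 3
duty/phase grid (252 feasible profiles), which preserves the full
amplitude/cutoff/mean structure.  These sizes keep a complete
verification pass within tens of minutes on one core while exercising
every code path; the enumerator emits the full 5 % grids when asked.

## Synthetic data

The generators exist so the whole chain can be built and tested without
access to trial hardware:

* `generate_trials()` — the 20-point operating grid (18 points in a
  speed-dependent flow band linearly interpolated between 0.5–4 L/min at
  6000 rpm and 3–8 L/min at 9000 rpm, plus 1 L/min anchors at 6000 and
  7000 rpm; the band is a fixture convention approximating the
  physiological range, not a measured quantity), three devices with
  multiplicative factors {1.5, 1, 0.95} (device 1 elevated, as observed
  across real builds) and lognormal HRI noise ($\sigma_{log}$ = 0.2
  default — multiplicative noise keeps hemolysis positive and matches
  the roughly constant coefficient of variation of repeated trials).
* `generate_samples()` — inverts the interval HRI definition into an
  hourly pfHb series (450 mL loop, HCT 35 %, Hb 10 g/dL, 6 h defaults)
  with additive Gaussian assay noise (0.5 mg/dL default).
* `generate_bench_data()` — a snake traversal of a speed × flow grid
  with holds and C²-smooth quintic ramps, head pressure computed with
  the analytic flow derivative so the noise-free dataset satisfies the
  hydraulic ODE exactly.  The smoothness and the 0.5 ms sampling are
  chosen so that the central-difference derivative used by the
  identifier is accurate enough for six-digit parameter recovery; bench
  noise is additive Gaussian on pressure.

All generators are pure functions of their seed.  What passing
recovery tests on these fixtures shows is that the *estimators* are
correct and well-conditioned; it does not validate the power law against
real blood, assay bias, blood aging, or trial-to-trial variance beyond
the assumed noise models.

## Numerical choices and edge cases

* Hydraulic identification scans integer exponents $x, y \in [-2, 4]$,
  solves each candidate by linear least squares on the pressure residual
  (flow derivative by central differences, one-sided at the ends), then
  re-simulates flow and selects by flow RMSE.  Candidates that are rank
  deficient (e.g. $x{=}1, y{=}0$ duplicates the linear flow column), have
  non-positive inertance, or diverge when re-simulated are dropped;
  constant-condition datasets are rejected as unidentifiable.
* `steady_flow()` inverts the static head for flow using the
  Citardauq quadratic form, which stays numerically stable and picks the
  branch continuous with the linear solution as $c \to 0$ (the physical
  operating branch; the other root is strongly negative).
* The effective-time update uses the end-of-step speed, as the
  accumulation rule is written.
* Particle damage at zero is mapped to zero effective time directly,
  avoiding `0^(1/â₂)` edge cases.
* `calibrate_f()` runs one washout plus a margin and verifies the
  aggregate is stationary to 1e-9 before taking the ratio.

## Known limitations

* The cardiovascular parameterization is generic heart failure, not a
  patient or the numeric model the topology cites; coupled absolute
  values are illustrative.
* Only forward flow is modelled; regurgitant and suction regimes abort.
* The power law is identified for one pump type; other pumps need new
  trials, $V_i$, $l_i$ and parameters.
* Atrial contraction and baroreflex adaptation are absent.
* The first-order profile filter bounds how differently the 2 Hz and
  20 Hz cutoffs can attenuate harmonics (ratio at most 10, reached only
  asymptotically); profile shapes, not a specific attenuation factor,
  are the modelled feature.
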