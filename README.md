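# hemolag

Trial-based, CFD-free hemolysis prediction for continuous-flow left
ventricular assist devices (LVADs).

Shear stress inside a rotary blood pump damages red blood cells and
releases plasma-free hemoglobin (pfHb) — a major adverse-event risk for
LVAD patients. The conventional way to predict this computationally is
CFD plus a shear-based damage law, which is far too expensive to sweep
operating modes or patient conditions. `hemolag` implements the
alternative: identify a damage model directly from in vitro hemolysis
trials of the physical pump, make it dynamic with a Lagrangian particle
scheme, and couple it to pump dynamics and a lumped-parameter
cardiovascular model. A complete operating-mode sweep then costs minutes,
not cluster-weeks. The package is written for device engineers and
modelling researchers studying hemocompatibility of rotary blood pumps;
all defaults describe the Sputnik1 axial-flow LVAD.

## The model in brief

The hemolysis rate index (HRI, %·mL/h) — the hourly pfHb rise normalized
to total hemoglobin, hematocrit and circuit volume — follows a modified
power law in pump flow Q and speed n:

    HRI / HRI_bar = c2 · (Q/Q_bar)^a2 · (n/n_bar)^b2

with c2 = 0.740, a2 = −0.394, b2 = 5.45 for the default pump (hemolysis
falls with flow, rises steeply with speed). Substituting the impeller
exposure time t_exp = Vi/Q gives the time-domain form
HRI = ĉ2·t_exp^â2·n^b2 used by the particle scheme: at each step dt one
particle enters the impeller region, every particle advances by
Δl = Q·li/Vi·dt and accumulates damage via an effective-time rule that is
consistent under time-varying speed, and the reported HRI is a corrected
mean over the region (correction factor f ≈ 1.393, analytically
1 + â2 = 1.394 in the continuous limit). The pump is modelled by a PT2
speed loop with dead time and a flow ODE
L·dQ/dt = a·Q + b·n² + c·Q^x·n^y − ΔP; the head pressure ΔP comes from an
8-compartment cardiovascular model with adjustable contractility (cf_lv),
systemic resistance (f_rsys) and heart rate.

## Worked example

Fit the power law from (synthetic) trials, then compare a constant-speed
run against a modulated one:

```r
library(hemolag)

# three devices x 20 operating points, hourly blood samples
trials <- generate_trials(sigma_log = 0.2, seed = 1)
std    <- standardize_hri(trials, hri_bar = 43.22)
fit    <- fit_power_law(std, q_bar = 4.65, n_bar = 7415, hri_bar = 43.22,
                        hri_col = "hri_std")
fit
#> Modified power-law fit (bisquare IRLS, 24 iteration(s))
#>   c2 = 0.6866, a2 = -0.4505, b2 = 5.997
#>   scaling: hri_bar = 43.22 %*mL/h, q_bar = 4.65 L/min, n_bar = 7415 rpm
#>   RMSE = 8.418 %*mL/h, R2 = 0.910 (n = 60)
```

The exponents land close to the generating values (−0.394, 5.45) from a
single noisy realization; `autoplot(fit)` draws the fitted flow curves
per speed.

```r
# coupled run at constant 7000 rpm, baseline heart failure (HR 75,
# cf_lv 0.25, f_rsys 1)
tr <- run_simulation(7000)
colMeans(cycle_metrics(tr)[, -1])[c("mean_hri", "pulse_pressure",
                                    "mean_lvad_flow")]
#>       mean_hri pulse_pressure mean_lvad_flow
#>      25.325494       6.619764       4.124260
```

A mean HRI of 25.3 %·mL/h at 4.1 L/min mean flow, with 6.6 mmHg residual
pulse pressure. Raising the speed raises HRI and flow and flattens the
pulse; speed modulation restores pulsatility at a hemolysis cost:

```r
specs <- enumerate_sweep(duty_grid = c(0.25, 0.5, 0.75),
                         phase_grid = c(0, 0.3, 0.6))
res <- modulation_sweep(specs)
summarize_modulation(res)
# at mean 7500 rpm: the max-pulse-pressure profile raises pulse pressure
# by ~176 % and mean HRI by ~14 %; the worst profile raises HRI by ~35 %
```

A thin command-line wrapper over these functions is installed at
`inst/cli/hemolag.R` (`simulate`, `sweep-constant`, `sweep-modulation`,
`calibrate-f`, `fit-trials`, `flow-range`, `make-fixtures`).

## Package layout

- `R/pump-model.R` — speed loop, hydraulics, parameter identification
- `R/hemolysis.R` — power law, reduction, Lagrangian scheme, calibration
- `R/trial-analysis.R` — interval HRI, standardization, robust fitting
- `R/cvs.R`, `R/simulate.R` — cardiovascular model, coupled runs, sweeps
- `R/profiles.R` — speed-modulation profiles and sweep enumeration
- `R/synthetic.R` — seeded generators for trials, samples, bench data
- `src/core.cpp` — the stepped kernels (Rcpp)
- `vignettes/hemolysis-modelling.Rmd` — the methods vignette
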