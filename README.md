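# anesdepth

Modelling the depth of anesthesia from dosing to the bispectral index
(BIS). `anesdepth` is aimed at pharmacometricians and anesthesia
researchers who need a self-contained, testable implementation of the
standard model chain behind BIS-guided drug titration, plus the
estimation machinery to identify it per patient:

* **Covariate PK model.** A three-compartment mammillary model whose
  volumes and clearances are functions of age, weight, height and sex:
  `V1 = 4.27`, `V2 = 18.9 − 0.391(age − 53)`, `V3 = 238` L;
  `Cl1 = 1.89 + 0.0456(wt − 77) − 0.0681(lbm − 59) + 0.0264(ht − 177)`,
  `Cl2 = 1.29 − 0.024(age − 53)`, `Cl3 = 0.836` L/min, with micro rate
  constants `k10 = Cl1/V1`, `k12 = Cl2/V1`, `k13 = Cl3/V1`,
  `k21 = Cl2/V2`, `k31 = Cl3/V3` and the sex-specific lean body mass
  `lbm`. Integration handles boluses as exact state jumps and
  piecewise-constant infusions with an adaptive solver.
* **Hill PD model.** `BIS = E0 − Emax · Ce^γ / (EC50^γ + Ce^γ)` on an
  effect-site concentration linked to plasma by
  `dCe/dt = ke0 (C1 − Ce)`.
* **Particle swarm identification.** `fit_pd()` estimates
  `(E0, Emax, EC50, γ)` (optionally `ke0`) per patient by minimizing
  the RMSE of the predicted BIS trace with a seeded, reproducible
  global-best swarm.
* **Gradient-boosted trees.** `gbdt_fit()` is a from-scratch forward
  stagewise ensemble of CART-style regression trees (squared loss,
  shrinkage, staged predictions) for regressing BIS from EEG spectral
  features; `eeg_features()` extracts per-epoch band powers, spectral
  edge frequency and spectral entropy.
* **Metrics and virtual cohorts.** `r_squared()`, `rmse()`, `mape()`;
  `generate_cohort()` builds elderly virtual patients with known
  ground truth so parameter recovery can be measured end to end;
  `run_experiment()` runs the full per-patient identification study
  and writes a tabular report.

## Worked example

Simulate a 74-year-old patient under an induction bolus plus
maintenance infusion, observe her BIS with monitor noise, and identify
the Hill parameters back from the trace:

```r
library(anesdepth)

p <- patient("p01", age = 74, weight = 68, height = 170, sex = "female")
pk_params(p)
#> Three-compartment PK parameters
#>   Volumes (L):       V1 = 4.27, V2 = 10.69, V3 = 238
#>   Clearances (L/min): Cl1 = 1.97, Cl2 = 0.786, Cl3 = 0.836
#>   Rate constants (1/min): k10 = 0.4614, k12 = 0.1841, k13 = 0.1958,
#>                           k21 = 0.07353, k31 = 0.003513

prot <- infusion_protocol(
  boluses  = data.frame(time = 0, dose = 85),                  # mg
  segments = data.frame(t_start = 0.5, t_end = 60, rate = 5.5)) # mg/min
pd_true <- pd_params(e0 = 93, emax = 72, ec50 = 2.6, gamma = 2.1)
times <- seq(0, 60, by = 0.1)

bis <- simulate_bis(p, prot, pd_true, times)
bis
#> BIS trace: 601 points over [0.00, 60.00] min; range [33.3, 93.0]

set.seed(2)
obs <- data.frame(time = times,
                  bis = pmin(pmax(bis$bis + rnorm(601, sd = 3), 0), 100))
class(obs) <- c("bis_trace", "data.frame")

fit <- fit_pd(obs, attr(bis, "conc"),
              control = pso_control(seed = 4), restarts = 3)
summary(fit)
#> Identified Hill PD parameters:
#>      e0    emax    ec50   gamma
#> 91.6561 65.6845  2.4703  2.4179
#> Swarm: 200 iterations x 3 restart(s); final RMSE 3.077
#> Fit over n = 601: R2 = 0.8732, RMSE = 3.077, MAPE = 4.056%
```

The identified curve sits at the monitor noise floor (RMSE ≈ 3 BIS
units for noise sd 3) and the parameters land close to the generating
values: the awake BIS `e0` within ~1.5 units, `ec50` within
0.13 µg/mL. R² of 0.87 means 87% of the observed BIS variance over the
hour is explained by the fitted concentration–effect curve.

A whole cohort study is one call:

```r
report <- run_experiment(run_config(n = 10, seed = 7, noise_sd = 3,
                                    out_dir = "run1"))
report   # per-patient R2 (%) and RMSE, summary row, >80% / >90% counts
```

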