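# kpdbmd

Kinetic-pharmacodynamic (K-PD) modelling of lumbar-spine bone mineral
density (BMD) under intravenous zoledronic acid, for pharmacometricians and
biostatisticians working on bisphosphonate dose optimization from
literature-aggregate data.

Zoledronic acid acts on bone over months while its plasma kinetics last
hours and its concentration at the target tissue is unobservable, so the
package models the *dose itself* as the driver of response. A virtual
compartment eliminates drug with first-order rate `KDE`; the resulting
virtual infusion rate `IR = KDE·A(t)` stimulates BMD synthesis through an
Emax model, attenuated by an exponential tolerance term:

    dA/dt = −KDE·A
    dR/dt = KS·(1 + IR/(EDK50 + IR))·e^(−K·t') − KD·R,   R(0) = KS/KD = BASE

with `t'` the time since first dose, `KS = BASE·KD` forced by the
pre-treatment steady state, and `EDK50` the infusion rate giving
half-maximal stimulation. On top of the structural model the package
provides:

- a population layer — log-normal inter-arm variability on `EDK50`,
  additive residual error, Laplace-approximate marginal likelihood, and
  maximum-likelihood fitting (`kpd_fit()`);
- a synthetic trial-arm generator emulating ten published study designs
  (`default_designs()`, `generate_dataset()`);
- model diagnostics: goodness-of-fit residuals, visual predictive checks,
  and a nonparametric bootstrap over arms (`kpd_gof()`, `kpd_vpc()`,
  `kpd_bootstrap()`);
- pooled exposure–response analysis of acute-phase-reaction (APR)
  incidence by dose with exact intervals and a Cochran–Armitage dose trend
  (`pooled_incidence()`, `dose_trend()`);
- stochastic regimen simulation against the ">3% BMD change from baseline"
  efficacy rule, with ranking of qualifying regimens by total administered
  drug (`simulate_scenario()`, `rank_regimens()`).

The ODE kernel is compiled (adaptive Cash–Karp RK45 with restarts at dose
events), so population fits on 40 arms take well under a second.

## Worked example

Simulate the twice-yearly 1 mg regimen at the published typical parameter
values, check the efficacy rule, and pool the 4 mg APR counts:

```r
library(kpdbmd)
fx <- load_fixtures()                 # packaged study tables + parameters

p <- published_params(base = 0.79)       # typical values, largest arm baseline
traj <- kpd_simulate(p, kpd_regimen(seq(0, 30, 6), rep(1, 6)), times = 0:72)
max(percent_change(traj))
#> [1] 8.709667                        # peak +8.71% from baseline, month 47

pooled_incidence(fx$apr, 4)$incidence_pct
#> [1] 50                              # 6/12 pooled APR events at 4 mg
```

The peak change comfortably exceeds the 3% threshold that marks a
clinically meaningful BMD response, with only 6 mg of total drug — the
basis for preferring low, frequent dosing, which the APR dose trend
(`dose_trend(fx$apr)`: increasing, p ≈ 0.008) reinforces.

Fit the population model to a synthetic 40-arm dataset generated at the
published values:

```r
d   <- generate_dataset(rep(fx$designs, 4), fx$pop, seed = 1)
fit <- kpd_fit(d, population_model(0.1, 0.005, 30000, 0.005, 0.3, 1e-4))
fit
#> Population K-PD fit (Laplace)
#>   40 arms, 184 observations; -2LL = -1262.3982
#>           estimate        se cv_pct fixed
#> kde    8.41706e-02 3.295e-02 39.140
#> kd     4.94124e-03 3.021e-04  6.113
#> edk50  5.23900e+04 1.373e+04 26.210
#> k_tol  7.61929e-03 5.008e-04  6.573
#> sigma2 4.35892e-05 5.178e-06 11.880
#> omega2 3.95515e-01 1.955e-01 49.440
#>   condition number: 33.47
```

The degradation rate (`kd`), half-maximal infusion rate (`edk50`) and
tolerance rate (`k_tol`) recover the generating values (0.00474, 41300,
0.00754) to within their sampling spread; `shrinkage(fit, d)` and
`kpd_vpc(fx$pop, d)` provide the corresponding diagnostics.

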