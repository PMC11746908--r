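# bcellkpd

Kinetic-pharmacodynamic (K-PD) modelling of rituximab-driven CD19+ B-cell
depletion and repletion in pediatric idiopathic nephrotic syndrome (INS).

Children with frequently-relapsing or steroid-dependent INS are treated
with the anti-CD20 antibody rituximab; relapse typically follows the return
of circulating B-cells, so the clinically important quantity is the time
course of the CD19+ count under a given dosing regimen. Rituximab
concentrations are rarely measured in children, so the package models the
dose itself: a virtual depot with first-order loss drives a sigmoid-Emax
stimulation of B-cell degradation in an indirect-response (turnover) model,

    dA1/dt = -Ke * A1
    dE/dt  = Kin - Kout * (1 + Emax * A1^g / (A1^g + ED50^g)) * E

with baseline `E0 = Kin/Kout` and B-cell repletion defined as the first
upward crossing of 10 cells/uL (1% of lymphocytes) after the last dose.

The package provides, for this model family:

* forward simulation of individual trajectories (`simulate_kpd()`,
  `repletion_time()`), with a closed-form depot and a stiffness-proof
  exponential-midpoint integrator;
* population (nonlinear mixed-effects) estimation by Laplace/FOCE-type
  approximate marginal likelihood (`kpd_fit()`), with power-law covariate
  effects, log-normal inter-individual variability, additive /
  proportional / combined residual error, stepwise covariate selection at
  the conventional ΔOFV thresholds 6.63 / 10.8 (`kpd_stepwise()`), and
  residual-model comparison (`compare_residual_models()`);
* model qualification: visual predictive check (`kpd_vpc()`),
  nonparametric bootstrap (`kpd_bootstrap()`), conditional weighted
  residuals and GOF tables (`cwres()`, `gof_table()`, `plot()` method),
  eta shrinkage (`eta_shrinkage()`);
* Monte Carlo dosing-regimen exploration (`simulate_regimen()`,
  `regimen_table()`, `covariate_sweep()`, `depletion_fraction()`);
* a synthetic-cohort generator with full ground truth
  (`generate_cohort()`), emulating a 59-child cohort contributing ~526
  CD19+ measurements, for estimation studies without any clinical data.

`kpd_reference_model()` returns the published population estimates
(depot half-life 14.1 d; B-cell half-life 99 d; Emax 389.7; ED50 1.31 mg;
Hill coefficient 6.65; baseline IgA acting on ED50 with exponent 1.39).

## Worked example

```r
library(bcellkpd)

m <- kpd_reference_model()
tr <- simulate_kpd(m$typical, data.frame(time = c(0, 7), amount = 307.5))
repletion_time(tr)
#> [1] 136.707

tab <- regimen_table(reference_regimens(bsa = 0.82), m, n = 1000, seed = 1)
tab[, c("label", "median", "p5", "p95")]
#>                           label median    p5 p95
#> 1           375 mg/m2 x4 weekly  158.1 113.3 218
#> 2           750 mg/m2 x2 weekly  151.8 104.7 208
#> 3           375 mg/m2 x2 weekly  135.2  92.0 192
#> 4                  750 mg/m2 x1  129.5  87.3 183
#> 5                  375 mg/m2 x1  119.5  77.3 170
#> 6                     100 mg x1   97.4  57.6 145
#> 7            six monthly 100 mg  251.8 210.1 301
#> 8  three 200 mg every 2 monthly  230.5 191.6 280
#> 9  three 150 mg every 2 monthly  224.0 180.9 276
#> 10 three 100 mg every 2 monthly  216.0 176.0 269
```

The typical individual on the standard course (two weekly infusions of
375 mg/m2 at the cohort's median BSA of 0.82 m2) crashes below 10 cells/uL
within two days and recovers past it around day 137; across 1000 simulated
individuals the median repletion day per regimen spans ~97 days (single
100 mg dose) to ~252 days (six monthly 100 mg doses), with mini-dose
regimens maintaining depletion far longer than the standard course at a
lower cumulative dose.

A full estimation round-trip on synthetic data:

```r
co  <- generate_cohort(cohort_config(seed = 1))   # 59 subjects, ~531 obs
fit <- kpd_fit(co$data, init = kpd_reference_model())
print(fit)        # estimates, RSE%, shrinkage, OFV
plot(fit)         # goodness-of-fit panels
kpd_vpc(co$data, fit$model, n_sim = 1000, seed = 1)
```

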