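---
title: "Kinetic-pharmacodynamic modelling of rituximab-driven B-cell depletion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic-pharmacodynamic modelling of rituximab-driven B-cell depletion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcellkpd)
```

## The model

Rituximab depletes circulating CD19+ B-cells; in children with idiopathic
nephrotic syndrome, relapse typically follows B-cell repletion, so the time
course of the CD19+ count under different dosing regimens is the clinically
relevant quantity.  Rituximab concentrations are rarely measured in this
population, so the package uses a kinetic-pharmacodynamic (K-PD) model: the
dose enters a *virtual depot* with first-order loss, and the depot amount --
not a measured concentration -- drives the pharmacodynamics:

$$\frac{dA_1}{dt} = -K_e A_1, \qquad
  \frac{dE}{dt} = K_{in} - K_{out}\left(1 +
    \frac{E_{max} A_1^{\gamma}}{A_1^{\gamma} + ED_{50}^{\gamma}}\right) E,$$

where $E$ is the CD19+ count (cells/uL), maintained by zero-order synthesis
$K_{in}$ and first-order degradation $K_{out}$ (an indirect-response or
turnover model), with baseline $E_0 = K_{in}/K_{out}$.  The depot stimulates
degradation through a sigmoid Emax (Hill) function: $ED_{50}$ is the depot
amount (mg) giving half the maximal fold-stimulation $E_{max}$, and $\gamma$
sets the steepness of the switch.  Because $\gamma$ is large and $ED_{50}$ is
on the milligram scale while a course delivers hundreds of milligrams,
B-cells crash within days of the first infusion, stay near the suppressed
quasi-steady state $K_{in}/(K_{out}(1+E_{max}))$ (about 1.5 cells/uL at the
reference estimates), and recover only when the depot has decayed to the
$ED_{50}$ scale -- which is what makes the time to repletion (first upward
crossing of 10 cells/uL, 1% of lymphocytes) depend on dose mainly through
$\log(\text{dose})/K_e$.

`kpd_reference_model()` carries the published population estimates for this
system (depot half-life 14.1 days, B-cell half-life 99 days, $E_{max}$
389.7, $ED_{50}$ 1.31 mg, $\gamma$ 6.65), log-normal inter-individual
variability on five parameters, a baseline-IgA power effect on $ED_{50}$
(exponent 1.39, reference 1.15 g/L; higher IgA means a larger individual
$ED_{50}$, weaker late stimulation, and earlier repletion), and combined
additive (2.56 cells/uL) + proportional (40%) residual error.  Reported
percent IIV magnitudes are interpreted as $100\times$ the SD of the
log-scale random effect, matching the stated normal-on-log model; the
additive residual SD is in cells/uL (the observable's unit).

## Numerics

The depot is available in closed form (superposition of bolus decays), so
the B-cell state solves a *scalar linear* ODE with time-varying coefficient
$k(t) = K_{out}(1 + S(A_1(t)))$.  The integrator is an exponential-midpoint
rule with Richardson extrapolation: each step is exact for frozen $k$, so
the fast depletion mode ($k \approx 2.7$/day versus recovery at 0.007/day)
poses no stability constraint.  Two regimes are used:

* **Simulation** (`simulate_kpd()`): adaptive steps controlled to
  `rtol = 1e-8`, `atol = 1e-10`; agreement with a reference stiff solver is
  at the 1e-9 relative level in the tests.
* **Estimation**: a *fixed, parameter-independent* time grid (0.25-day base
  step, coarsened up to 8-fold with time since the last dose).  A fixed grid
  makes the discretized likelihood a smooth function of the parameters --
  essential for finite-difference gradients -- at a relative trajectory
  error near 2e-4, well below the residual noise.

Infusions are instantaneous boluses into the depot (day-scale dynamics make
hour-long infusions negligible); integration restarts at each dose time with
a continuous state.  Repletion times are bracketed on the output grid and
refined by bisection to 0.01 day, re-integrating from the bracket.  The
upward crossing is searched after the last dose, so brief inter-dose
rebounds under sparse low-dose regimens are ignored.

## Estimation

`kpd_fit()` maximizes an approximate marginal likelihood of the
Laplace/FOCE family.  Each subject's random effects $\eta$ (log-normal,
independent across parameters) are profiled by an inner search for the mode
of the joint density -- Levenberg--Marquardt descent followed by a short
Newton polish on the analytic gradient, using first-order parameter
sensitivities integrated alongside the state.  The curvature term uses the
expected-information (Gauss--Newton) Hessian (`method = "foce"`) or an
exact finite-difference Hessian at the mode (`method = "laplace"`; this is
the variant compared against adaptive Gauss--Hermite quadrature in the
tests).  With all IIV set to zero the objective reduces exactly to the
closed-form Gaussian likelihood.

Two numerical facts shaped the optimizer design, and both are worth knowing
when interpreting fits:

* With five random effects and roughly nine observations per subject, a
  subject's conditional density can have *several modes*.  The objective
  value therefore depends on which mode the inner search lands on.
  Reported OFVs re-find the modes from $\eta = 0$ and from the fit's
  incumbent state, keep each subject's best, and a fit never returns a
  point whose reported OFV is worse than its starting value.
  `kpd_stepwise()` additionally passes the incumbent etas between the fits
  it compares, so likelihood-ratio statistics are not driven by one fit
  knowing a better mode branch than the other.
* The outer surface has long curved valleys (e.g. $E_{max}$--$ED_{50}$--
  $\gamma$ trade-offs).  The outer optimizer is BFGS on log-transformed
  parameters (covariate exponents untransformed), with warm-started
  forward-difference gradients when random effects are present and exact
  sensitivity-based gradients in the no-IIV (pure regression) case, plus a
  restart from the incumbent.

Relative standard errors come from the observed information
(finite-difference Hessian on the estimation scale; the SE of a log equals
the relative SE of the natural value).  Missing observations (`MDV = 1`)
contribute nothing to the likelihood.  Empirical-Bayes eta shrinkage is
reported as $100(1 - \mathrm{SD}(\hat\eta)/\omega)$ for parameters with
IIV.

Stepwise covariate selection (`kpd_stepwise()`) uses the conventional OFV
thresholds: forward inclusion at a drop of 6.63 ($\chi^2_1$, $p<0.01$) and
backward exclusion at 10.8 ($p<0.001$).  Candidate exponents start from the
shrinkage-corrected regression of empirical-Bayes etas on the log
covariate (the standard screening estimate, with the parameter's IIV
shrunk by the variance the regression explains), with fresh-start and
zero-start fallbacks, and when a candidate fit discovers a deeper basin
the base model is refitted from it before the likelihood-ratio statistic
is formed -- otherwise basin luck, not the covariate, would drive
selection.

## The synthetic cohort generator

No individual-level clinical data are published for this system, so
`generate_cohort()` creates virtual cohorts with the statistical structure
the estimation machinery assumes, plus the complete ground truth for
recovery studies.  Defaults emulate the study population: 59 children;
baseline IgA normal (1.15 +/- 0.52 g/L, truncated above 0.05); BSA
log-normal with median 0.82 m2 and geometric CV 20% (the spread is a
synthetic choice -- only the median is published); two weekly infusions of
375 mg/m2 capped at 500 mg; and a monitoring schedule of a pre-dose sample,
a day-14 sample, then visits every 30 days (+/- 3 days uniform jitter)
through day 240, about 531 observations in total, matching the published
~526.

The schedule deliberately follows subjects *through* recovery.  An earlier
design that stopped sampling at individual repletion (plus one confirmatory
visit) left the recovery rate $K_{out}$ practically unidentifiable: the
likelihood then prefers a degenerate region (fast $K_{out}$ with a tiny,
shallow $ED_{50}$ switch) that the sparse recovery limb cannot refute, and
parameter recovery fails through no fault of the estimator.  Observing the
recovery limb is also what a clinic monitoring for relapse would do.

Simulated observations below zero are redrawn once and then clamped at zero
(the observable is a count-like concentration).  This truncation at the
depletion nadir (predictions ~1.5 cells/uL against a residual SD of ~2.6)
biases $E_{max}$ down and $K_{in}$ up by a measurable but tolerable amount;
it is confined to the generator, and the estimation likelihood remains the
unconstrained Gaussian, exactly as specified.

What passing recovery tests do show: with this design and the reference
variability, median biases across ten cohorts stay within +-20% for
$K_e, K_{in}, K_{out}$ and within +-50% for $E_{max}, ED_{50}, \gamma$
(whose published RSEs are themselves 15-58%).  What they do not show:
performance under the real study's sampling times (unpublished), under
model misspecification, or for the relapse-prediction analyses, which are
outside this package's scope.

## Dosing-regimen exploration

`simulate_regimen()` samples individuals from the population model (all
etas drawn; covariates fixed at their reference values by default -- IgA
1.15 g/L -- since the published simulations are silent on whether IgA was
sampled), integrates the *latent* trajectory without residual error, and
summarizes the first upward crossing of 10 cells/uL after the last dose by
the median and 5th-95th percentiles.  Residual error is excluded here
because repletion is a threshold crossing of the biological state, not of a
noisy measurement; the VPC, by contrast, simulates observables and
therefore includes residual error.  Individuals that never deplete (large
positive $ED_{50}$ etas under small doses) are excluded from the
percentiles and reported as a fraction.  No per-infusion cap is applied to
the reference regimen set: the published cumulative-dose arithmetic
(750 mg/m2 x 1 at BSA 0.82 = 615 mg) is inconsistent with a 500 mg cap, so
the cap is an option rather than a default.

A worked table (1000 individuals per regimen, seeded) reproduces the
published medians within a few percent and their ordering exactly; the
acceptance script (`scripts/acceptance.R`) recomputes it from scratch.

## Qualification tools

* `kpd_vpc()`: simulates replicate datasets at the design of the input data
  (residual error included), bins observations in time (default: 8
  quantile-based bins -- the published analysis does not state its binning),
  and compares observed 5th/50th/95th percentiles with the simulated 90%
  confidence band of each percentile.  Negative simulated observations are
  retained, consistent with the unconstrained residual model.
* `kpd_bootstrap()`: nonparametric subject-level resampling with
  replacement, refitting each resample; medians and 2.5/97.5 percentiles
  across converged resamples, with an instability flag above 20%
  non-convergence.  Whether the covariate model should be re-selected per
  resample is not specified in the source analysis; the implementation
  refits the given model structure.
* `gof_table()`, `cwres()`, `plot.kpd_fit()`: observed versus population
  and individual predictions, and conditional weighted residuals
  (first-order conditional linearization about the empirical-Bayes etas,
  decorrelated by the per-subject covariance) against prediction and time
  after dose.

## Worked example

```{r example, eval = FALSE}
# a synthetic study cohort and a population fit
co <- generate_cohort(cohort_config(seed = 1))
fit <- kpd_fit(co$data, init = kpd_reference_model())
print(fit)
plot(fit)

# dosing-regimen exploration (the published comparison)
tab <- regimen_table(reference_regimens(bsa = 0.82), kpd_reference_model(),
                     n = 1000, seed = 1)
tab
```

Problem sizes used in the shipped tests are scaled to desk hardware: ten
59-subject cohorts for recovery and selection studies, 400-1000 VPC
replicates, 50-resample bootstraps on compact scenarios, and 1000
individuals per simulated regimen.

## Known limitations

* The approximate marginal likelihood is of the FOCE/Laplace family; no
  exact (quadrature or Monte Carlo) marginalization is attempted beyond the
  one-eta oracles in the tests.
* Eta correlations are fixed at zero (no off-diagonal IIV is published).
* The published point estimates cannot be reproduced exactly without the
  clinical dataset; estimation quality is assessed by parameter recovery on
  synthetic cohorts instead.
* Per-subject conditional multimodality is intrinsic to this model at
  sparse designs; the deterministic reporting policy makes it visible
  rather than hiding it, and occasional fits flagged `converged = FALSE`
  should be inspected or refitted from other starts.
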