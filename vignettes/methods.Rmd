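---
title: "Modelling T2DM prevention: model, calibration and scenario engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling T2DM prevention: model, calibration and scenario engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The compartmental model

`t2dprev` implements a deterministic, population-level model of type 2
diabetes mellitus (T2DM) for a national population stratified by sex, 5-year
age band (0–4 … 75+), the joint status of three modifiable risk factors
(obesity, defined as BMI > 30 kg/m²; current smoking; physical inactivity),
disease status, and physical-activity (PA) intervention status. Because only
susceptible (diabetes-free) people can enrol in the PA intervention, the
effective state space is 2 sexes × 16 bands × 8 risk combinations × 3
disease/intervention states = 768 compartments.

The flows, each conserving persons between its source and sink:

1. **Entry** into the youngest band (susceptible, risk-free, no
   intervention) at a rate `entry0 · exp(g (t − 2016))` per sex — a smooth
   growth curve standing in for births and the demographic momentum of a
   young population.
2. **Aging** between adjacent bands at 1/5 per year (the reciprocal of the
   band width); the open 75+ band has no aging outflow.
3. **Background mortality** μ(sex, age) from every compartment.
4. **Risk-factor acquisition and cessation**: per-factor hazards
   η_k(sex, age) (off → on) and ρ_k(sex, age) (on → off) acting
   independently on the joint combination, preserving disease and
   intervention status. Correlation between factors therefore emerges only
   dynamically; the 2016 initial state is built with within-stratum
   independence.
5. **T2DM incidence** from each susceptible compartment to the T2DM
   compartment with the same sex/age/combination, at hazard
   λ₀(sex, age) · RR_ob^[obese] · RR_sm^[smoker] · RR_ia^[inactive] ·
   RR_pa^[PA], i.e. multiplicative relative risks under independence.
   Conversion drops the intervention label: T2DM compartments are not
   intervention-stratified.
6. **T2DM-related excess mortality** ν(sex, age) among prevalent cases.
7. **PA recruitment** from (susceptible, none) to (susceptible, PA) in the
   target bands (15–64 by default), at a time-varying rate set by the
   scenario engine. There is no exit pathway from the intervention: no
   attrition mechanism is modelled, so PA coverage is a ratchet.

Smoking is a binary current-smoker state with no former-smoker memory; BMI
is dichotomised, so reductions in mean BMI that do not cross the obesity
threshold are invisible to the model — both are deliberate simplifications
that keep the state space identifiable from prevalence data.

## Parameters

| family | units | default / provenance |
|---|---|---|
| `entry0`, `g` | persons/yr, /yr | solved from the two population anchors |
| `mu` | /yr | Gompertz `m0 e^{slope·age}`, m0 = 4e-4, slope = 0.075, females ×0.85 |
| `eta_k`, `rho_k` | /yr | η seeded from quasi-stationary balance, then fitted; ρ priors 0.02 (obesity), 0.04 (smoking), 0.05 (inactivity) |
| `lambda0` | /yr | seeded analytically, then fitted (sex-specific scales) |
| `rr` | – | RR_ob 4.3, RR_sm 1.4, RR_ia 1.4, chosen so each factor's population-attributable fraction matches the magnitude its 2016 prevalence implies |
| `rr_pa` | – | 0.61 / 0.66 / 0.68 / 0.74 / 0.85 for vigorous / low / moderate / leisure / walking intensity |
| `nu` | /yr | shape `e^{0.04(age−50)}`, scale fitted; anchored by the 2016 case-fatality rate |

## The synthetic study population

The generator (`t2d_config()`, `generate_demography()`,
`generate_targets()`, `generate_initial_state()`) emulates the study
conditions rather than any microdata: a 15–64 population of 144,066 in 2016
growing to 221,627 by 2050; 2016 aggregate prevalences of 41.4% (obesity),
16.2% (smoking), 46.0% (inactivity) and 16.7% (T2DM); and a 2016
case-fatality rate of 8.6 per 1000 person-years. Age profiles are logistic
on the logit scale with configurable midpoint and steepness, scaled so the
pyramid-weighted 15–64 aggregate matches the configured value exactly; sex
differences enter as female:male odds ratios (smoking strongly male-skewed
at 0.08, obesity and inactivity mildly female-skewed, as is typical of
regional survey data). The age pyramid decays as a half-Gaussian in age
(scale 32 y, median age ≈ 22), and the entry growth rate is solved so the
demography-only projection hits the 2050 anchor; infeasible anchor pairs
(unreachable under zero migration) raise an error.

Age-specific prevalence targets are repeated across the target years
(2016, 2019, 2026, 2036, 2046), encoding the baseline assumption that
age-specific risk-factor prevalence stays constant so that aggregate trends
are driven by population aging alone. The early 2019 target year makes the
relaxation rate of the risk-factor dynamics visible to the fit, which is
what separates η from ρ scales.

What the generator does **not** emulate: real survey noise structure and
design effects, migration, cohort effects in smoking uptake, continuous
BMI, or secular trends in risk factors. Passing tests therefore demonstrate
internal consistency of the pipeline under the stated conditions, not
predictive validity for any real population.

## Calibration

`t2d_fit()` minimises a weighted least-squares loss over 11 log-scale
multipliers: sex-specific scales of λ₀ and of each η_k, a shared smoking
cessation scale, a ν scale, and an entry-flow scale. Prevalence residuals
are absolute (fraction scale); population and case-fatality residuals are
relative, since their units differ by orders of magnitude. Acquisition and
cessation are jointly only weakly identified by prevalence trajectories, so
ρ is fixed to configurable priors for obesity and inactivity and fitted only
for smoking — the standard identifiability compromise when a single survey
round anchors the fit. Optimisation uses bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`) from an analytic seed (quasi-stationary per-band
balance equations), with optional seeded log-uniform multi-starts within
±50%. On noiseless model-generated targets the fit recovers every fitted
rate to well under 1% from ±20%-perturbed starts (the test suite asserts
5%).

## Scenario engine and the prevalence controller

Scenario targets are *trajectories*, not mechanisms: a relative reduction F
moves the aggregate 15–64 prevalence of a factor linearly from its 2016
level p₀ to p₀(1 − F) over the scale-up window, held thereafter; F = 0
("halt") pins the prevalence at p₀, which is an active intervention because
the baseline aggregate drifts upward with aging. The mechanism enforcing a
target is a per-step proportional controller: every 0.5 years it solves, in
closed form, for a factor x such that scaling cessation by x and
acquisition by 1/x (susceptible compartments in the target bands only)
moves the aggregate prevalence to its target at the step's end, after
measuring the baseline drift with one evaluation of the right-hand side.
x is clamped to [0.1, 10], so both multipliers stay within [0, 10];
saturation (an unattainable target) produces a warning carrying the
achieved trajectory, never a silent failure. Tracking error at reporting
years is well under the 0.2-percentage-point tolerance asserted in the
tests. PA coverage is tracked the same way, with the recruitment rate
solved per step and floored at zero (no exit).

Two denominator conventions are defensible for "prevalence of factor k":
the whole 15–64 population or its diabetes-free subset. The intervention
acts on susceptibles, but public-health targets are population
prevalences, so the controller defaults to whole-population denominators;
`build_forcing(..., denominator = "susceptible")` switches.

## Numerical choices

- Solver: adaptive Dormand–Prince (`deSolve`, `ode45`), rtol 1e-8,
  atol 1e-10; a fixed-step classical RK4 mode (dt = 0.01 y) exists for
  cross-checking, and an 8-compartment closed subsystem is checked against
  its matrix exponential. All Runge–Kutta methods preserve the person-count
  linear invariant exactly, so conservation holds to rounding error.
- Calibration inner simulations run at rtol 1e-6 / atol 1e-8 with `lsoda`
  for speed; the returned fit re-evaluates residuals and is insensitive to
  this at the 1e-7 level.
- Negative-state guard: counts below −1e-9 persons abort with the offending
  time and compartment; values in [−1e-9, 0) are clamped to zero at
  reporting times.
- Reported percentages round half-up at one decimal and are always computed
  on unrounded values (rounded inputs make printed relative reductions
  internally inconsistent).
- Controller cadence is 0.5 y; reporting is yearly, 2016–2050.

## Problem sizes in the test suite

The full 768-compartment system is used throughout. The noisy-recovery
property runs 5 seeded replicates at noise SD 0.5 percentage points; the
Monte-Carlo unbiasedness check of the target generator uses 200 replicates
of three representative targets; oracle comparisons integrate 5-year
horizons. These sizes were chosen to exercise every code path while keeping
the suite around a minute.

## Known limitations

- No uncertainty quantification: the model is deterministic and the fit
  reports no intervals, matching the study design it implements.
- Exact reproduction of any published scenario table is out of scope: the
  original parameterisation is not public, so the package reproduces the
  structure, signs, orderings and magnitudes of the published analyses on
  its own calibrated synthetic configuration.
- T2DM complications, non-national resident populations, health
  expenditure, continuous BMI and behavioural uptake dynamics beyond the
  prescribed ramps are out of scope.
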