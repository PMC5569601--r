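---
title: "Modelling gastric emptying with viscosity-driven secretion and a duodenal brake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gastric emptying with viscosity-driven secretion and a duodenal brake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`gastrosim` couples three submodels of the digestion of a liquid meal.

**Stomach (stirred tank).** Three mass pools — nutrient `StomN` (g), liquid
`Stomliq` (g) and thickener `StomLBG` (g) — empty with a common first-order
rate `gamma` (1/s).  The liquid pool receives gastric secretions:

    dStomN/dt   = -gamma * StomN
    dStomliq/dt =  Ksec(mu) - gamma * Stomliq
    dStomLBG/dt = -gamma * StomLBG

The chyme is assumed perfectly mixed, so the thickener concentration is
`C = StomLBG / (Stomliq / rho_w)`, expressed in g/100 ml, and viscosity
follows the power law `mu = a_L * C^b_L` (defaults `a_L = 2` Pa s,
`b_L = 4.21`, which pin 1 g/100 ml to 2 Pa s and 1.5 g/100 ml to ~11 Pa s
— the anchor points of the locust-bean-gum rheology the model was built
on).  Secretion responds to viscosity as `Ksec = lambda_s * mu^b + S_b`,
with `S_b` the basal rate (g/s of secreted liquid, density of water).

**Small intestine (plug flow).** The nutrient linear density `s(z, t)`
(g/m) on `z ∈ [0, L]` (default `L = 2.85` m) is advected at the mean
velocity `u = 1.7e-4` m/s and absorbed at first-order rate `K_a` (1/s).
Emptied nutrient enters as a point bolus at `z = l_0` (default 2.5 cm, the
scale of a gastric ejection bolus; results are insensitive to `l_0` within
1–5 cm because the signal of interest is the integral below).  The
absorption rate `A(t) = K_a * ∫ s dz` (g/s) is the quantity the gut
senses.

**Duodenal brake.** The base emptying rate `gamma_0` is gated by `A(t)`:
emptying stops when absorption exceeds a ceiling `A_max` (g/s).  The
logical switch is `gamma = 0` if `A > A_max`, else `gamma_0`.  A smooth
variant `gamma = gamma_0 / (1 + exp(tau_A * (A - A_max)))` equals
`gamma_0/2` exactly at the ceiling and converges to the logical switch as
`tau_A` grows; `tau_A = 5e6` s/g makes the two numerically
indistinguishable.  (The sigmoid is stated with the orientation that
reproduces the logical switch in the large-`tau_A` limit; the commonly
printed form with the opposite sign inside the exponential inverts the
brake and cannot be meant.)

**Base-rate hypotheses.** `gamma_0` itself is either a fitted constant
(feedback-only model) or one of five linear combinations of viscosity,
total gastric volume `V` (m^3) and secretion rate, named
`VISC_PLUS_VOL`, `VOL_PLUS_C`, `VISC_PLUS_C`, `SEC_PLUS_C`,
`SEC_PLUS_VOL` (see `emptying_hypothesis()`).  `SEC_PLUS_C`
(`gamma_0 = m_sec * Ksec + C1`) is the preset used by the combined-meal
parameter tables.

## Numerics

Time marching is explicit (forward Euler); space is discretised with a
backward (upwind) difference, so nothing propagates towards the pylorus
and the zero-gradient inlet stays empty.  Defaults: `dz = L/570` (5 mm)
and `dt = 0.9 / (u/dz + K_a)`, 90% of the positivity bound; the simulator
halves `dt` and restarts if a state goes negative or non-finite (the
gastric equation's own bound `gamma * dt < 1` is checked at run time
because `gamma` is state-dependent).  The chosen step is reported in the
trajectory's `dt_used` attribute and in run manifests.

Mass bookkeeping is exact by construction: the lumen mass is the
trapezoidal integral of the density, absorption per step is
`dt * K_a * mass`, and outflow through `z = L` is the flux of the last
trapezoid panel, `u * dt * (s[N-1] + s[N]) / 2`.  With the bolus entering
at an interior node this telescopes, so

    stomach + lumen + absorbed + outflow = input

holds to round-off at every step; the test suite asserts a 1e-10 relative
bound and a 1e-3 bound survives even long brake-chattering runs.

Within a step the order is: algebraic state (concentration, viscosity,
secretion, `gamma_0`), then `A(t)` from the previous field, then the
gastric Euler update, then injection and transport.  This explicit
coupling delays the brake's reaction by one step, so during regulation
`A(t)` chatters around `A_max` with amplitude `~K_a * gamma * StomN * dt`
and the time-averaged absorption sits a few percent above the ceiling at
the default step (about 5% on the 100 g preset).  Reducing `dt` shrinks
both the chatter and that bias; the packaged defaults keep the whole test
battery inside a few minutes on one CPU.

## Packaged parameter presets

`inst/extdata/presets/` ships three YAML tables: eight fitted
feedback-only glucose conditions (`preset_feedback("a")`–`"h"`, 15–114 g
drinks), the non-nutrient secretion optimum with its Monte-Carlo
mean ± 2 sd bounds (`preset_secretion()`), and four combined-meal fits
(`preset_meal("LVN"|"HVN"|"LVC"|"HVC")`).  Condition "a" was fitted as a
pure exponential, so its preset carries `A_max = Inf`, `K_a = 0`.

The published tables do not state the meals' liquid loads or initial
viscosities, so the presets adopt: 500 g liquid (the 500 ml drinks of the
underlying in-vivo studies), 80 g glucose-equivalent for nutrient meals
(~323 kcal) and 16 g for controls (~64 kcal), initial viscosity 0.06 Pa s
for low-viscosity meals and 11 Pa s for high-viscosity ones — the top of
the range over which the rheology law was fitted.  (The high-viscosity
source meal was nearer 30 Pa s; running the presets at 11, 20 or 30 Pa s
changes no qualitative behaviour, so the value inside the fitted range is
kept.)

## Synthetic data

`generate_dataset()` emulates the gastric-content time series the fits
were originally run against: the preset's trajectory sampled every 10 min
to 60 min, plus additive Gaussian noise whose standard deviations are
percent-of-initial-mass replicate scatter (the printed values for the two
high-glucose conditions; a flat 10% where none were printed — the 6–17
unit magnitude typical of such data).  `nonnutrient_viscosity_set()`
emulates the four-meal viscosity design: viscosity sampled every 10 min
and a measured total-content half-time with 5% coefficient of variation;
noise enters through the content-derived half-time by default, with
optional multiplicative lognormal viscosity noise (`visc_sigma`).  These are
replicate-level perturbations of a mean curve, not between-subject
spread, which is several-fold larger in the source figures.  Passing
round-trip tests on such data therefore demonstrates the estimation
machinery, not robustness to full inter-individual variability — real
data also bring non-Gaussian error, drift in meal composition, and
measurement-modality biases (a scintigraphy tracer follows the nutrient;
MRI volume follows total content) that the generator does not model.

## Estimation design

Fitting uses bounded Levenberg–Marquardt (`minpack.lm::nls.lm`, the
`lsqnonlin` analogue) with a log-space latin-hypercube multi-start,
followed by a Nelder–Mead polish.  Two features are specific to the
brake's geometry:

* **The SSE is a fine staircase in `A_max` and `K_a`.**  With a hard (or
  effectively hard, `tau_A = 5e6`) switch, changing these parameters
  alters the discrete on/off pattern only at isolated values, so
  gradients carry no information.  `fit_feedback_model()` therefore adds
  (i) a deterministic profile over `A_max` candidates — the regulated
  phase's mass slope (which equals `-A_max` while the brake regulates),
  the brake-off absorption peak, and a coarse log ladder — each with the
  remaining parameters refitted, and (ii) cyclic multiplicative
  line-scan refinement (`coord_refine`) that descends the staircase
  envelope.
* **Self-consistency studies use a resolvable sigmoid.**  For
  noise-free round-trip tests the smooth switch is used on both the
  generating and fitting side with `tau_A = 2e3` s/g, the sharpest value
  whose sigmoid width (~4/tau_A g/s) the default step actually resolves;
  the forward map is then smooth and recovery is exact.  At
  `tau_A = 5e6` the discretised dynamics are bang-bang and the zero-SSE
  optimum sits on a measure-zero needle no bounded-budget optimiser
  reliably hits to 1%.

The packaged rate tables share parameters across meal sizes within a
study, and the estimation follows that design: an `observation_set` can
hold several experiments (see `bind_observation_sets()`) fitted jointly
with shared rates, each experiment keeping its own input mass.  The small
meal pins `gamma0` (it empties exponentially), the large meal pins
`A_max` (its regulated slope) — separately, neither identifies all three
parameters well.

The secretion model is fitted on the composite objective: viscosity
residuals normalised per-experiment by the initial viscosity, plus, per
experiment, `sqrt(2) * (0.5 - Stomtot(t_half)/liq0)` so the squared term
carries the printed factor of two.  AIC is the least-squares form
`n log(SSE/n) + 2p` and hypothesis ranking reports
`exp((AIC_min - AIC_i)/2)` relative likelihoods.  All five hypothesis
forms have two constants, so with the shared secretion parameters every
candidate has `p = 5` and ranking is effectively by SSE; on noisy
replicates the secretion-based and viscosity-based forms are close
competitors (their fitted optima differ by less than the replicate noise
contributes to the objective), which mirrors the near-unity relative
likelihoods the original analysis reported — form identification from
this design is genuinely marginal.

`run_monte_carlo()` perturbs observations (uniform on ±sd by default,
the literal reading of noise drawn "from the range" of replicate
deviation; Gaussian optional), refits from the unperturbed optimum, and
summarises samples as mean ± 2 sd bounds (flooring at zero optional and
off by default, matching the published bounds which go below zero for no
parameter).  Warm starting is deliberate: it reproduces the published
protocol, in which parameters the data do not constrain stay at the
optimum and show "little variation", while cold restarts would measure
optimiser scatter instead of noise response.

## Sensitivity analysis

`sensitivity_series()` implements the one-sided normalised finite
difference `S*(t) = [f(theta(1+eps)) - f(theta)] / (eps * f0)` with
`f` the gastric nutrient trajectory, `f0` the meal's input mass and
`eps = 0.01` by default.  Both runs share one grid and step; the logical
switch is used so the spike morphology is preserved.  Spike amplitudes
depend on `dt` (a perturbation shifts brake switchings by whole steps),
so only locations and zero-patterns are asserted in tests: brake
parameters have identically zero sensitivity whenever regulation never
engages, and spikes occur only after the first engagement.

## Known limitations

* Single-phase liquid meals only: no gastric filling period, no
  solid/liquid phase separation, no enzymatic viscosity change, no
  hormonal (CCK/ghrelin) or glucose–insulin coupling.
* `K_a` is constant along the intestine; radial mixing and motility are
  subsumed into its fitted value.
* With the high-viscosity combined-meal parameters the brake cannot
  engage before the 80 g meal's glucose half-time (absorption reaches the
  ceiling only after ~44 g have emptied), so glucose half-times are flat
  in load for that preset even though they rise steeply for the
  low-viscosity one; the load-dependence there is carried almost entirely
  by the total-content curve through secretion volume.
* Problem sizes used throughout the tests: the 5 mm / 0.9-CFL default
  grid, horizons of 1–4 h, 50-replicate recovery and selection studies,
  and Monte-Carlo runs of 25–50 iterations (the production default is
  5000; the API exposes `n_iter`).
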