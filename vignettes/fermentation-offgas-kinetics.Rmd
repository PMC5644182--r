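---
title: "Off-gas growth kinetics and metabolite profiling for batch fermentations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Off-gas growth kinetics and metabolite profiling for batch fermentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermkin)
```

## The problem

Submerged batch cultivations of filamentous fungi are routinely characterized
through the exhaust gas: the CO2 fraction of the off-gas tracks metabolically
active biomass continuously, where dry-weight sampling is sparse, destructive
and often too thin to resolve a short exponential phase. fermkin implements
the quantitative-physiology workflow built on that signal:

1. a **gas balance** turning exhaust CO2 (%), airflow (vvm) and working volume
   into a CO2 evolution rate (CER, mmol/L/h) and its running integral,
   accumulated CO2;
2. **phase segmentation** — lag-phase end, exponential-growth window, time of
   the CO2 maximum, and the duration of the non-exponential growth phase that
   filamentous fungi show when pellets or clumps form;
3. **kinetics** — maximum specific growth rate from dry weight
   (semi-logarithmic regression), maximum CO2 production rate from accumulated
   CO2, biomass yield on substrate, and replicate summaries;
4. rule-based **LC-MS metabolite profiling** — area/intensity thresholds,
   two-of-three replicate presence, accurate-mass dereplication against a
   compound library, and per-stage production profiles;
5. a **synthetic-data generator** providing batch fermentations and feature
   tables with exact ground truth, so every stage above is testable without
   instrument data.

## The growth model behind the generator

The generator treats a batch culture as a piecewise kinetic model:

* **lag** (`t < lag_h`): biomass constant at the inoculum level `x0`; only
  maintenance respiration.
* **exponential** (`lag_h <= t < t_pellet_h`): `dX/dt = mu_max * X`,
  substrate consumed as `dS/dt = -(1/y_sx) dX/dt`.
* **non-exponential** (`t_pellet_h <= t`, optional): constant-rate accretion
  `dX/dt = nonexp_rate`, the simplest model that reproduces the observed
  "CO2 still rising, but no longer exponentially" plateau approach after
  pellet or clump formation. No mechanistic claim is attached to it; pellet
  mass-transfer physics is out of scope.
* **starvation** (after substrate exhaustion): growth stops and the
  metabolically active fraction decays at `starvation_decay` (default
  0.15 /h), producing the post-peak CO2 decline.

CO2 evolution couples to growth as `CER = y_cx * dX/dt + m_co2 * X_active`,
and the exhaust percentage follows from the ideal-gas conversion at the
25 degC cultivation temperature (molar volume 24.465 L/mol); during the
exponential phase both terms are proportional to `exp(mu t)`, which is why
the slope of `ln(accumulated CO2)` estimates `mu_max`.

Defaults mirror a 1 L reactor with 0.9 L working volume, 15 g/L glucose,
airflow ramped 0.1 to 0.9 vvm over the first 1200 min, and an inoculum of
about 1e9 spores/L (a few mg dry weight per litre, `x0 = 0.003 g/L`).
Noise: multiplicative lognormal on the off-gas culture signal (default CV
1%, process mass spectrometers are sub-percent precise), additive Gaussian
truncated at zero on dry weight and glucose (default SD 0.1 g/L), and a
between-replicate lognormal CV (default 5%) on `mu_max` and `lag_h`.
Dry weight and glucose share sampling times by default — one broth sample
serves both assays — which also keeps the yield's endpoint matching
consistent.

Integration uses fixed-step RK4 at one tenth of the off-gas interval. The
regime ODEs are linear, so the RK4 one-step map is a constant growth factor
applied vectorized; regime boundaries (lag end, pellet transition, substrate
exhaustion) are located in closed form, and the tests corroborate the
trajectory against an independently written closed-form oracle and a plain
RK4 loop.

## Segmentation: the decisions that were genuinely open

**Lag end.** "First run of k consecutive samples above a CO2 threshold" needs
a k (unstated in common practice); we default to `k = 3` for robustness to
single-sample sensor glitches. The threshold must be commensurate with the
signal: the function default is 6% (a value meaningful for signals peaking
near or above that level), while the built-in scenarios — whose exhaust CO2
peaks at a few tenths of a percent at 0.1-0.9 vvm and 15 g/L glucose — set
scenario-specific thresholds (0.1-0.25%) placed in the upper half of their
exponential rise. A failed detection is an explicit, stage-labelled error,
never a silent zero.

**Exponential window.** The window is fit by OLS on `ln(accumulated CO2)`
(not instantaneous CER: integration suppresses sensor noise, and once the
signal is far above the pre-lag baseline the integration constant is
negligible — tested on simulations). Acceptance requires `R2 >= 0.99` and at
least 3 points. Two selection modes exist:

* `anchor = FALSE`: the *longest* window anywhere at or after the anchor
  satisfying the criteria (earliest start on ties). This free search is kept
  as a documented mode and is verified against exhaustive enumeration, but it
  has a failure mode we measured explicitly: on runs with a long
  non-exponential phase, `ln(acc CO2)` over the linear-accretion regime curves
  so slowly that a 50+ hour window there can reach R2 = 0.99 and out-compete
  the true exponential window, and even without a transition the longest
  window systematically overruns the exhaustion kink by hours.
* `anchor = TRUE` (default, used by `segment_run()`): the window starts at
  the detected lag end and extends as far as the criteria allow, capped at
  the CO2 maximum. This pins the fit to the exponential rise, and the R2
  criterion then localizes the kink where exponential growth stops. On the
  built-in scenarios this recovers the transition time within one sampling
  interval on clean data.

**CO2 maximum.** A centered moving average (default 1 h) rejects noise, but a
pure smoothed argmax is systematically early at the rise-then-crash corner a
batch culture produces at substrate exhaustion (the window mixes post-crash
samples in). `find_co2_max()` therefore takes the raw argmax within one
smoothing window of the smoothed argmax; ties resolve to the earliest time.
All reported times are sample timestamps — no sub-sample interpolation.

**Non-exponential duration** is the time from the end of the accepted
exponential fit to the CO2 maximum, floored at zero.

## Kinetics

* `mu_from_dryweight()` regresses `ln(DW)` on time inside the exponential
  window and reports the estimate only when `n >= 3` and `R2 >= 0.96`;
  otherwise the value is flagged absent and never imputed. The pipeline
  additionally applies a 0.2 g/L quantification floor (twice the default
  noise SD — filter/dry/weigh measurements below that carry no usable
  log-scale information).
* `co2_rate()` is the slope of the accepted accumulated-CO2 fit; it is
  available whenever segmentation succeeds, which is exactly what makes it
  the usable growth-rate proxy when the exponential phase is too short for
  three dry-weight samples.
* `yield_sx()` is biomass gain over substrate consumption across the growth
  window (default: lag end to CO2 maximum), endpoints matched to the nearest
  sample within 2 h. Because both series are sampled from the same broth
  draws, the matched endpoints coincide and the ratio is exact on clean data.
* Replicate summaries use the sample SD (n - 1); absent values are excluded
  but counted.

## The built-in scenarios

* `dispersed-DM` — dispersed growth on defined medium, no transition:
  exponential until substrate exhaustion, non-exponential duration 0. Off-gas
  every 6 min.
* `pelleted-DM` — pellet formation at 40 h, exhaustion at 90 h. Off-gas every
  30 min.
* `vulpinum-like` — reconstructs a pelleted defined-medium narrative:
  exponential until 36 h, CO2 still rising through a 74 h non-exponential
  phase, maximum just after 110 h. Within the linear-accretion model this
  narrative constrains the parameters: the maintenance-driven CER climb over
  the non-exponential phase, `m_co2 * (X_final - X_pellet)`, must exceed the
  CER drop at the transition, `y_cx * (mu * X_pellet - nonexp_rate)`,
  otherwise the global CO2 maximum would sit at the transition instead of
  substrate exhaustion. The scenario (mu = 0.22/h, lag 12 h, x0 = 0.01 g/L,
  y_cx = 0.5, m_co2 = 0.04) satisfies this with the exhaustion placed just
  after 110 h. The two narrative scenarios set `replicate_cv = 0`: they
  reconstruct one observed geometry, and replicate-level biology would move
  the transition/exhaustion times the narrative fixes.

Problem sizes in the test suite follow the same choices: recovery studies run
100 triplicates per growth rate in {0.15, 0.20, 0.30}/h at 2% off-gas CV and
0.1 g/L dry-weight noise; the acceptance script runs 30 triplicates per rate.
Ground truth for the lag rule is defined by applying the same detector to the
noise-free twin of each signal, since the configured lag (where growth
starts) precedes any observable gas signal by design.

## What the generator does and does not emulate

It emulates: triplicate structure, ramped airflow, realistic signal
magnitudes, multiplicative off-gas noise, sparse noisy samples, replicate
biology, pellet-transition geometry, planted LC-MS features with bounded mass
jitter and guaranteed-separated noise masses. It does not emulate: drifting
or autocorrelated sensor error, diauxic growth, pH/base dynamics, oxygen
limitation, morphology itself, isotopologues, in-source fragments, or
retention-time drift. Passing recovery tests therefore demonstrates the
correctness of the estimators under the stated noise model, not instrument
robustness on arbitrary real data.

## Metabolite profiling rules

Candidates are the features of the latest-time sample with area strictly
above 500,000 and intensity strictly above 10,000 counts. Candidates are then
searched for in all other samples *without* any threshold, and a compound
counts as present when it matches in at least two of three replicates.
Matching tolerances default to 10 ppm m/z and 0.1 min retention time
(QTOF-appropriate; unstated in common practice, hence configurable), and all
matches carry their signed ppm error so tolerance sensitivity is auditable.
Dereplication considers [M+H]+, [M+Na]+ and [M+NH4]+ and preserves isobaric
ambiguity. Identifications are mass matches only; confirmation against
physical standards is not a computation.

## Numerical notes and limitations

* Trapezoidal integration of the CER is exact for linear integrands and
  within 0.1% of the closed form for exponential signals at minute-scale
  sampling; scheme choice is immaterial at these densities.
* The window search uses prefix-sum OLS; the exhaustive mode is O(n^2) per
  series and intended for the short series where it is verified, the
  anchored mode is O(n).
* Whether accumulated CO2 should be inlet-corrected is instrument-dependent;
  both modes are supported (`inlet_co2_pct = 0` disables subtraction).
* With `nonexp_rate` close to `mu * X_pellet` the transition is
  slope-continuous in `ln(acc CO2)` and *no* R2-based rule can localize it
  sharply; the scenarios avoid that degenerate geometry, real data may not.
* The lag rule's 6% function default is intentional and documented; it is
  not reinterpreted as 0.6%.
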