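---
title: "Methods: from raw biologging and doubly-labelled water to daily energy expenditure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw biologging and doubly-labelled water to daily energy expenditure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`plungedee` estimates the daily energy expenditure (DEE) of a plunge-diving,
colony-breeding seabird by combining single-sample doubly-labelled-water
(DLW) energetics with accelerometer, depth and GPS biologging. This vignette
documents the models the package implements, the assumptions behind them,
the tunable constants and their defaults, what the synthetic-data generator
does and does not emulate, and the numerical choices a maintainer should
know about.

## The signal stage

**VeDBA.** Movement-related acceleration is summarized as vectorial dynamic
body acceleration: the Euclidean norm of the three axis signals after
subtracting each axis's *static* component, a centered running mean over a
3 s window (`static_window_s`, default 3 s — long relative to a wingbeat at
~5 Hz, short relative to posture changes). Windows are truncated rather
than dropped at the record edges so that every minute of the deployment has
a DBA value and the minute grid stays aligned with the depth and GPS
streams. VeDBA is averaged over 1 s (smoothing) and summed over each
calendar minute to give the DBA stream; partial minutes are flagged.

Two numerical points. First, subtracting a finite running mean leaves a
small leakage when the window does not hold an integer number of wingbeat
periods; for a pure sinusoid of amplitude A the per-sample mean of VeDBA
approaches the rectified-sine mean 2A/pi with an error well under 1% for
the default window. Second, at 50 Hz a 5 Hz wingbeat is sampled only 10
times per cycle, and the discrete mean of |sin| then deviates from 2A/pi by
up to ~3% purely through aliasing — a property of the sampling, not of the
implementation; the unit tests therefore check the closed form on a finely
sampled sinusoid.

**Wingbeat frequency** is the frequency of the maximum-magnitude non-DC
FFT bin of the heave axis over 30 s windows (`wingbeat_window_s`,
resolution 1/30 Hz). Window starts default to a 1 s stride; the pipeline
uses non-overlapping 30 s windows, which changes the per-minute median by
at most one bin on sustained flight. Per-minute thinning uses the median of
windows whose center falls in the minute. An all-constant window has no
non-DC peak and returns 0 Hz with a flag. No detrending is applied beyond
excluding the DC bin, so a window of pure sensor noise returns an
essentially uniform draw over bins — the colony and resting states'
wingbeat distributions must therefore be interpreted as "no dominant flap
signal", not as a physical frequency.

**Dive fraction** is the proportion of 1 Hz depth samples in the minute
deeper than the wet threshold (`wet_threshold_m`, default 0.1 m, the depth
sensor's noise floor): submerged 30 s of 60 gives 0.5.

**Track streams.** GPS fixes are interpolated to exact 60 s ticks,
piecewise-linearly by default (deterministic, and exact for
constant-velocity motion); a natural cubic spline is available as a
smoother for meandering tracks. The colony stream is 1 within 0.5 km of
the colony and 0 beyond 1 km; the threshold rule leaves the 0.5-1 km band
unclassified, and this implementation assigns it 0 (at sea) — a documented
convention, not an assertion about the field protocol. Step length is the
great-circle distance between consecutive 1-min positions, assigned to the
*later* minute: a fix reflects where the bird is at that instant, so the
displacement arriving at a fix is the movement performed during that
minute. Steps whose endpoints were interpolated across a missing fix are
imputation rather than observation and are left missing, to be
marginalized by the classifier. Distances are great-circle on a sphere of
mean Earth radius for lon/lat input and planar for km offsets.

## The behavioural classifier

A four-state hidden Markov model (colony, commuting, foraging, resting)
runs over the four per-minute streams — colony presence, wingbeat
frequency, dive fraction, step length — assumed conditionally independent
given the state. DBA is deliberately not a classification stream; it is
joined to the decoded states afterwards, so the time-energy models are not
circular.

Emission families: Bernoulli for the binary colony stream; zero-inflated
gamma for wingbeat frequency and step length (non-negative, right-skewed,
with genuine zeros possible); zero/one-inflated beta for dive fraction
(point masses at 0 and 1 plus a beta density between). The families sit
behind one interface (density, weighted M-step, mean, simulation) and are
pluggable. The package's starting values are plausible stand-ins for a
plunge-diver — colony presence nearly deterministic per state, commuting
wingbeat near 5 Hz, dives only while foraging, commuting steps near 600 m
per minute — and are labelled as package defaults, not field estimates.

Fitting is Baum-Welch EM with per-step scaling (finite log-likelihoods at
10^5 minutes), closed-form transition and initial-distribution updates,
and exact weighted maximum-likelihood emission updates (Newton on the gamma
shape; quasi-Newton on the beta parameters) wrapped in a generalized-EM
safeguard: a parameter update that would lower its weighted likelihood is
rejected, so the log-likelihood trace is non-decreasing to floating-point
accuracy. Streams that are degenerate within a state keep their starting
parameters ("pinned") with a warning. Records from multiple birds are
pooled with the initial distribution resetting at each bird boundary.
Decoding is Viterbi in log space with ties broken toward the lower state
index; minutes with every stream missing are imputed from the transition
structure and flagged. Because state labels are only identified up to
permutation, evaluation against ground truth aligns labels by the
maximum-overlap permutation (exhaustive — the state set is small).

## DLW energetics (single-sample, one-pool)

The protocol: a separate *equilibrium* set of birds is bled at background,
injected, and bled again after a 1 h equilibration in a dark box; the
*deployed* birds give only a final sample at recapture, their initial
enrichment being predicted from the equilibrium set's ordinary
least-squares mass-enrichment line per isotope. The prediction is trusted
when Pearson's |r| exceeds 0.7 for both isotopes (the validity gate); the
fit warns when predicting outside the fitted mass range.

The calculations use the standard one-sample, one-pool forms: turnover
k = ln[(I_init − I_bg)/(I_final − I_bg)]/T_eff with the 1 h equilibration
deducted from the sampling interval (`equilibration_h`, configurable);
plateau dilution N = Mol_inj (I_inj − I_init)/(I_init − I_bg); the final
pool by the percentage-mass method N_f = N_o m_final/m_initial with the
interval average N = (N_o + N_f)/2; and
rCO2 = 1000[(N/2.078)(k_o − k_d) − 0.0062 k_d N] mmol h⁻¹, appropriate for
birds under 4 kg. All coefficients live in one `dlw_constants()` record so
alternates can be swapped.

Unit conventions deserve a note. The energy conversion defaults to
22.4 ml CO2 per mmol (molar gas volume) and 27.3 J per ml CO2 (the
energetic equivalent for protein-rich piscivore diets), giving
DEE = rCO2 × 22.4 × 27.3 × 24/1000 kJ day⁻¹; a per-mol convention
(factor 2240) can be selected through the constants record, and the
caloric equivalent is likewise configurable. Mass-specific DEE divides by
body mass, by default the mean of initial and final mass (symmetric over
the interval; initial-only is available). Enrichments enter the turnover
only as background-subtracted differences — a constant offset to the three
blood values leaves k unchanged — but the dilution space compares blood
values against the injectate, so the same offset does shift N; both
behaviours are tested.

A negative rCO2 (possible when k_o ≤ k_d after the fractionation
correction) is physiologically invalid; the value is returned for
diagnostics with a validity flag rather than silently dropped.

## Time budgets and the candidate model set

Totals are standardized to a day as value × 24 / sampling hours, applied
identically to times and DBA (deployments shorter than 20 h warn). The
candidate set contains twelve designs: five partitions of the four
activities — fully separate; colony vs at-sea; colony+resting vs
commuting+foraging; and the two three-group variants — under two predictor
kinds (summed hours; summed activity-specific daily DBA), plus an
intercept-only null and a total-daily-DBA null. Only the set's size and a
few members are canonical, so the partitions are configurable.

Time-budget designs are fitted with the intercept fixed at zero: when
every hour of the day is attributed to an activity there is no residual
"no-activity" energy, and each coefficient is that activity's
mass-specific metabolic rate in kJ h⁻¹ g⁻¹. DBA designs keep a free
intercept, interpretable as the expenditure at zero movement, a proxy for
basal metabolic rate. Fits are ordinary least squares; the Gaussian
log-likelihood uses the maximum-likelihood variance, and the AICc
parameter count k includes that variance (a convention that must be fixed
for the ranking to be well defined):
AICc = −2 logLik + 2k + 2k(k+1)/(n−k−1), undefined (and excluded with a
warning) when n − k − 1 ≤ 0. Predictive strength is the Pearson
correlation between fitted and observed mass-specific DEE; it is undefined
for constant predictions (the intercept-only null) and flagged rather than
forced. Activity-specific rates convert to whole-animal watts at a
reference mass (kJ h⁻¹ / 3.6) and to multiples of a basal metabolic rate
supplied as configuration (default 4.39 W) — the allometric formula behind
that number is outside the package's scope. Group comparisons (sex,
day/night) use the ordinary least-squares two-group contrast, identical to
the pooled-variance t framework.

One behaviour is worth flagging for interpretation: when the true rates of
merged activities are similar, several partitions become nearly
observationally equivalent and compete within a few AICc units — rankings
then legitimately show multiple designs with dAICc < 2, and the selection
tests therefore assert recovery of the generating design against its
*noise-augmented supersets* (designs that split its groups), which is the
comparison AICc's penalty is about, rather than against statistical twins.

## The synthetic cohort generator

The generator defines the study conditions under which the package is
validated. Defaults: 10 equilibrium birds and 20 deployed single-sample
birds; deployments drawn uniformly on 46-61 h; a minute-resolution
behavioural Markov chain whose structural zeros route all colony arrivals
and departures through commuting flight and whose stationary distribution
spends ~18.8 h per day at the colony (~80% colony attendance), ~4.0 h
commuting, and well under an hour each foraging and resting; per-bird
effort heterogeneity as a lognormal multiplier (sdlog 0.35) on the
colony-departure rate; sex-dimorphic masses (females ~1650 g, males
~1350 g, s.d. 75 g); true activity-specific metabolic rates in the ratio
1 : 2.7 : 4.6 : 2.6 (colony : commuting : foraging : resting) anchored at
a colony rate of 0.0325 kJ h⁻¹ g⁻¹, so the cohort's mean mass-specific
DEE sits near 1.1 kJ day⁻¹ g⁻¹.

Tracks are laid out in polar coordinates about the colony: the first half
of a trip's commuting minutes move radially outward at 10 m s⁻¹ and the
second half return, foraging and resting minutes drift locally, colony
minutes jitter within 0.2 km, and every at-sea minute is kept beyond
1.05 km — so the colony data stream is geometrically unambiguous by
construction. Waveforms put gravity on the heave axis plus a state-specific
sinusoid (5 Hz at 1 g commuting, 5.5 Hz at 1.2 g foraging, a 0.3 Hz / 0.15 g
wave rock while resting on water) with Gaussian sensor noise (0.05 g per
axis); plunge dives are rectangular pulses (1-4 m deep, 3-15 s, in 70% of
foraging minutes) during which flapping pauses; GPS adds 20 m noise and
drops fixes with probability 0.02.

Isotope panels are generated by *inverting* the one-pool equations: the
bird's true initial enrichments come from a linear mass-enrichment
relation (its coefficients consistent with a ~65% body-water pool diluting
a 0.055 mol dose), deuterium turnover is the baseline water turnover
(0.035 h⁻¹), oxygen turnover is solved from the DEE-implied CO2
production, and final enrichments follow exponential washout. With zero
noise the DLW module recovers the assigned DEE to floating point; the
default cohort applies 5% lognormal noise to the measured DEE and
analytic-precision-scale scatter (3 ppm 2H, 1.5 ppm 18O) to the
equilibrium samples, so the cohort's total DLW measurement error matches
the intended 5% condition. Because the single-sample method differences
two turnover rates, equilibrium-relation scatter amplifies strongly into
rCO2 — scatter at tens of ppm would triple the effective noise, which is
exactly the error structure that makes the single-sample protocol
sensitive to its equilibrium regression in the field.

What the generator does *not* emulate: aerodynamics or biomechanics (the
wingbeat is a fixed sinusoid, not a gait model), thermoregulation, tides
or wind drift, dive-shape structure (descent/bottom/ascent), device
failures beyond GPS gaps, within-state variation in flap amplitude
(acknowledged as a free parameter — no field estimate exists for it), or
any dependence of DEE on sex beyond mass. Passing tests on these cohorts
therefore demonstrate correctness of the computations and recoverability
under clean, well-separated conditions; they do not demonstrate that field
data of this species would classify at the same accuracy or correlate at
the same strength.

## Problem sizes used in validation

Chosen to exercise every stage at meaningful scale: the full 50 Hz sensor
chain runs on 3 birds × ~2 days for classifier accuracy and time-budget
recovery; the DLW round trip uses 100 random birds; model-selection and
coverage checks use 100 seeded replicates of 20-bird cohorts generated at
the summary level (budgets drawn with realistic independent between-bird
spread — commuting 1-6 h, foraging and resting 0.2-2 h per day — so that
all four rates are identifiable); determinism checks run the whole
pipeline twice on an 8-bird, ~22 h-deployment cohort, the smallest size at
which the richest candidate design remains estimable.

## Known limitations

- The HMM assumes conditional independence of streams given the state;
  wingbeat frequency and step length are physically coupled in flight, and
  the model relies on the state to absorb that correlation.
- One pooled HMM is fitted across birds (initial distribution resetting
  per record); per-bird or hierarchical fits are out of scope.
- Transition probabilities are homogeneous in time — no diel covariates —
  although the simulated species forages only by day.
- The equilibrium regression predicts initial enrichment from mass alone;
  body-condition effects on dilution space are not modelled.
- AICc ranking assumes Gaussian residuals on the mass-specific scale; no
  mixed-effects or phylogenetic extensions are provided.
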