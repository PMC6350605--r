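---
title: "Personalized glucose prediction: models, training and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized glucose prediction: models, training and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

glucopred predicts the blood glucose level (BGL) of insulin-treated diabetic
outpatients from a lifestyle log: timestamped meals with a decomposed
nutrient content, subcutaneous insulin injections, continuous glucose
monitor (CGMS) readings at 5-minute cadence and sparse fingerstick
self-measurements. This vignette is the package's own account of the
science: the two coupled models, the numerics, the personalization
machinery, the synthetic validation data, and the known limitations.

## The coupled model

### Digestion

Meal carbohydrate reaches the blood through a two-compartment
(stomach--intestine) mass-balance model over five nutrient classes:
free monosaccharides, starch portions each with their own glycemic index
(GI), lipids, proteins and fibers. All balances are first order:

* Gastric emptying moves every stomach species to the intestine at rate
  $k_{ge} / (1 + c_L L + c_P P + c_F F)$, where $L, P, F$ are the lipid,
  protein and fiber masses currently in the stomach. Fat, protein and
  fiber therefore *retard* carbohydrate delivery without contributing
  glucose themselves, which is what distinguishes a mixed meal from a pure
  glucose drink.
* Starch is hydrolyzed to monosaccharide in the intestine at rate
  $k_{hyd} \cdot GI$, so high-GI starch appears earlier.
* Free intestinal monosaccharide is absorbed at rate $k_{abs}$; the
  absorbed flux, converted by $1000/180.16$ from g/min to mmol/min and
  divided by the glucose distribution volume $V_G \cdot kgBW$, is the
  appearance term $\Delta a_{Monosac}(t)$ driving the glycemia model.

Because every balance is linear, overlapping meals superpose exactly; a
meal eaten while the previous one is still being digested simply adds mass
to the compartments. Defaults ($k_{ge} = 0.028$, $k_{hyd} = k_{abs} =
0.023$ min$^{-1}$, $c_L = c_P = 0.02$, $c_F = 0.05$ g$^{-1}$) give
appearance peaks 30--90 min after a meal, the physiologically expected
range; they are population-level constants (digestion is not altered by
diabetes) and are configurable but never trained.

### Glucose--insulin control

Plasma glucose $G$ (mmol/l) and insulin $I$ (pM) follow a
delay-differential system with one subcutaneous depot pair per injection:

$$\frac{dG}{dt} = -K_{xgi}\, G I + \frac{T_{GH}}{V_G} + \Delta a_{Monosac}(t)$$

$$\frac{dI}{dt} = -K_{xi} I + \frac{T_{iGmax}}{V_I} f\!\big(G(t - \tau_G)\big)
 + \sum_d \frac{S2_d}{V_I\, t_{max,I,d}}$$

$$\frac{dS1_d}{dt} = -\frac{S1_d}{t_{max,I,d}}, \qquad
  \frac{dS2_d}{dt} = \frac{S1_d - S2_d}{t_{max,I,d}}$$

with the sigmoidal pancreatic response
$f(G) = (G/G^*)^\gamma / (1 + (G/G^*)^\gamma)$ evaluated at glucose
delayed by $\tau_G$ minutes. An injection of $D$ IU adds
$D \cdot 6000 / kgBW$ pmol/kgBW to the first depot of a fresh pair
(1 IU = 6 nmol, the standard convention); the pair's $t_{max,I}$ is the
insulin product's time-to-maximum absorption, resolved from a shipped
registry (rapid analog 55 min, regular 90 min, NPH 300 min, long-acting
analog 600 min). Basal insulin is represented exactly like a bolus with a
long $t_{max,I}$. Keeping one depot pair per administration lets products
with different absorption kinetics overlap correctly.

One structural note: written as a plain input term, insulin injection
must *add* mass to $S1$ for the cascade to deliver anything to plasma;
the package applies injections as positive impulses into $S1$, which
also makes the injected dose exactly equal the depot residual plus the
cumulative plasma appearance (a tested invariant).

The nine glycemia parameters and their literature-optimized defaults are
documented in `?glycemia_params`. With no meals and no injections the
system has a unique basal steady state, found by `steady_state()` from the
algebraic balances; the default parameters give a hyperglycemic resting
point (as expected for an insulin-dependent patient without therapy).

### Numerics

Both models are co-integrated on one clock by a fixed-step classical RK4
scheme (compiled core), default step 1 min. The delay term uses a
per-step history buffer of $G$ with linear interpolation; pre-history is
the constant initial value. This requires $\tau_G \geq$ step (enforced).
Events — meals, injections, model restarts — are applied as discrete
state updates at their (grid-rounded) timestamps, with outputs recorded
*before* events at coincident instants, so a reported prediction never
already contains the fingerstick it is evaluated against. Starch portions
and depots for the whole window are allocated up front with zero mass,
keeping the ODE dimension fixed. Initial conditions: $G_0$ is the first
logged measurement (else the steady-state $G$), $I_0$ the steady-state
insulin, empty stomach and depots. Tiny integrator-noise negatives on
mass-like states are clamped at $10^{-9}$; a non-finite or out-of-range
trajectory is an error (or an infinite fitness during training, so that
degenerate candidates are rejected rather than crashing the search).
Step halving changes a 6-h trajectory by under $10^{-6}$ mmol/l, and the
trajectory agrees with an independent 0.01-min explicit-Euler oracle to
$10^{-3}$ mmol/l (both tested).

## Model restarts

A patient on insulin therapy measures BGL with a fingerstick before each
main meal. The prediction protocol exploits this: at every fingerstick
the model's $G$ is reset to the measured value and the delay history is
re-seeded, while $I$, $S1$, $S2$ and the digestion state are left alone
— so insulin evolution and digestion overlapping two meals remain
correctly modeled while accumulated glucose error is discarded. Restarts
are on in the training fitness and in the default evaluation protocol;
`full_run(..., restart = FALSE)` measures the open-loop behaviour.

## Personalization

Parameters are trained as dimensionless multipliers of the reference
values, bounded to $[0.2, 5]$ by default to exclude clinically impossible
values. The trainable subsets follow the model's sensitivity ranking
(reproducible with `ofat_sensitivity()`): the 3 dominant parameters
$(K_{xgi}, K_{xi}, V_I)$, the 6 that matter $(+\,T_{GH}, V_G,
T_{iGmax})$, or all 9. The fitness is the full-window prediction RMSE
(restarts on) against all CGMS samples, in mmol/l.

Three searches are shipped, composable as a pipeline
(`glucose_fit()`): a brute-force grid (7 additive steps of 20%, i.e.
$\{0.4, \dots, 1.6\}$; $7^3 = 343$ evaluations for 3 parameters), a
real-coded genetic algorithm (tournament of 3, BLX-0.5 crossover,
per-gene Gaussian mutation with $\sigma = 0.1$, elitism 1, candidates
clipped to bounds; *fast* preset: population and generations 10,
crossover 0.90, mutation 0.01; *slow* preset: population and generations
50, crossover 0.90, mutation 0.20), and a Nelder--Mead simplex
refinement (max 100 iterations, initial simplex spanned by +5%
perturbations, never returning a worse point than its start). The GA is
seeded; identical seeds give identical results.

### Identifiability — read before interpreting multipliers

The model is *exactly* invariant under the joint scaling
$(K_{xgi}, V_I) \to (c\,K_{xgi}, c\,V_I)$: substituting $J = V_I I$
removes $V_I$ from the insulin balance (both its sources carry
$1/V_I$), and glucose only sees the product $(K_{xgi}/V_I)\, G J$. The
steady-state initialization preserves the symmetry. Consequently only
$K_{xgi}/V_I$ and $K_{xi}$ are identifiable from glucose data in the
3-parameter space: the fitness is flat along a ridge, any point of which
the GA and simplex may return. On noise-free synthetic patients the
package recovers the identifiable combinations essentially exactly
(tested to 2%), while individual $K_{xgi}$ and $V_I$ multipliers land
anywhere on the ridge; the brute-force grid typically returns the planted
point only because the discrete grid intersects the ridge there. Treat
trained multipliers as a predictive parameterization, not as measured
physiology — a caveat that applies to any fit of this model family to
BGL data alone.

## Diurnal profiles

Insulin sensitivity varies with the circadian rhythm; prediction errors
of a time-constant model concentrate in the night hours. The package
therefore supports a diurnal profile: the day is split into four periods
(0--6, 6--12, 12--18, 18--24 h), one multiplier per period is trained for
the profiled parameter ($K_{xi}$ by default), and the four knots,
anchored at the period midpoints, are smoothed by a periodic cubic spline
so the curve is $C^1$ across midnight. Spline overshoot beyond the
multiplier bounds is clipped rather than re-fit. A constant profile of 1
reproduces the unprofiled model bit for bit (tested).

Per-period training masks the RMSE to the CGMS samples of one period
while always simulating the whole window, because digestion and insulin
kinetics cross period boundaries. Since the insulin state carries about
80 minutes of memory, fitting periods one at a time against a flat rest
of the day biases the knots toward each other; `train_diurnal()` instead
runs a coordinate descent (default two sweeps) in which each period's
candidate is evaluated through the actual spline built from the current
estimates of the other knots. On noise-free synthetic patients this
recovers planted knot patterns to well under 5%.

## Evaluation

`error_metrics()` reports mean absolute error, maximal error, error
variance and RMSE. Clarke Error Grid Analysis (`ega_classify()`)
classifies each prediction--reference pair into clinical severity zones
A--E using the published grid geometry in mg/dl (conversion factor
18.016), with boundary points assigned to the less severe zone; A+B is
the "clinically acceptable" fraction. Protocols: `full_run()` (continuous
simulation, restarts on or off), `meal_wise_test()` (model restarted
fresh at each meal from the nearest CGMS anchor within 10 min, previous
events discarded, horizons 1--6 h — errors grow with the horizon because
overlapping absorption is deliberately ignored), `cross_validate()`
(1- or 2-day sliding training window advanced in 3-h steps, validated by
the pooled 1-h meal-wise RMSE on the meals outside the window), and
`improvement_ttest()` (Welch two-sample test at 5%).

## Virtual patients

The study's clinical logs are not publicly available, so validation runs
on synthetic patients (`generate_virtual_patient()`): three main meals
per day with jittered times and sizes drawn from a small built-in food
table, a carbohydrate-proportional but deliberately imperfect bolus
(±20% dosing jitter — patients dose by experience), once-daily basal
insulin at bedtime, a fingerstick before each main meal, and CGMS
readings every 5 min. True parameters are planted or sampled log-normally
(median 1) within the identification bounds. CGMS noise is multiplicative
white Gaussian plus an AR(1) drift whose amplitude grows linearly over
the six-day sensor life; the defaults were calibrated once so that
typical traces show ≈1.4 mmol/l median absolute difference and ≈17% mean
relative difference from truth, the error level reported for this sensor
class in outpatient care. Fingerstick noise is 5% CV (no quantitative
meter error was available; this is a stated placeholder). Everything is
deterministic under a seed.

What passing tests on these patients show — and what they do not: the
generator shares the forward model with the predictor, so recovery tests
validate the identification machinery under realistic noise, not the
biological adequacy of the model itself; real logs add meal-logging
errors, unlogged activity and stress, and CGMS artifacts (pressure
dropouts, calibration steps) that the noise model does not emulate.

## Problem sizes and defaults used in the shipped checks

The test suite and the acceptance script run on 1--4-day virtual
patients at the 1-min integration step: the slow GA preset is exercised
on 3-day logs (864 CGMS samples; ~2,600 fitness evaluations), diurnal
training on 3-day logs with the fast preset, and cross-validation with
10 window positions on a 4-day log. These sizes keep every property of
interest observable — multi-day windows, overlapping meals, several
sensor days of drift — at desk-scale runtimes.

## Known limitations

* No physical activity, stress, renal glucose clearance or incretin
  effects; the digestion rate constants are committed plausible values
  with the documented structure, not fitted to tracer data.
* Basal insulin as a long-$t_{max,I}$ bolus is a first-order stand-in for
  truly flat basal kinetics; patients on pump therapy are out of scope.
* The $(K_{xgi}, V_I)$ ridge above; with 6 or 9 trained parameters
  further near-degeneracies appear (e.g. $T_{GH}/V_G$ at fixed meal
  response), so multiplier interpretation degrades as the space grows.
* CGMS noise is treated as exogenous: the training fitness weights all
  samples equally and does not model sensor bias, so a trained model
  partly absorbs systematic sensor error.
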