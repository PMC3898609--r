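---
title: "Analysis of intracellular calcium transients: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysis of intracellular calcium transients: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catransient)
```

## The measurement problem

Fluorescent calcium indicators report intracellular calcium as changes in
emitted light. In a paced cardiac myocyte the recorded signal is a *calcium
transient*: a flat diastolic baseline, a fast upstroke on stimulation, and a
slower decay back to rest as calcium is resequestered and extruded. The raw
digitizer output is not directly interpretable: it contains fluorescence
from the whole optical field and is in arbitrary units that depend on dye
loading and optics. Quantitative physiology needs two things from it —
absolute or relative calcium *levels* (diastolic, systolic, amplitude) and
the *kinetics* of the decay, summarized by one or two exponential rate
constants.

This package implements that workflow end to end: signal preparation, level
measurement, and multi-exponential regression of the decay with nested-model
comparison, plus a seedable synthetic-transient generator so every stage can
be validated against known ground truth.

## Signal preparation

All preparation starts with subtraction of **background fluorescence**, the
signal of the field of view with the cell absent. Every formula below is
written in terms of the background-subtracted fluorescence $F$; the package
enforces this by tagging each trace with its preparation state and applying
subtraction exactly once. If a background *recording* is supplied rather
than a scalar, it is reduced to its mean first — the background is assumed
steady, and a single scalar per channel is what the subtraction model
supports.

Three conversions are available:

* **Ratiometric indicators** (e.g. fura-2): the per-sample ratio of the two
  background-subtracted channels, $R = F_{nom}/F_{denom}$, cancels
  dye-concentration and path-length artifacts. A denominator sample at or
  below zero after subtraction aborts with the offending sample index.

* **Calibration to absolute calcium** (non-ratiometric indicators such as
  fluo-3), through the indicator binding curve
  $$[\mathrm{Ca}] = \frac{F \, K_d}{F_{max} - F},$$
  with $K_d$ the dissociation constant (nM) and $F_{max}$ the fluorescence
  at saturating calcium. The map is strictly increasing on $(0, F_{max})$;
  at $F = F_{max}/2$ it returns exactly $K_d$. Samples at or above $F_{max}$
  abort the calibration — the formula diverges there, and silently emitting
  negative concentrations would be worse than failing. Samples at or below
  zero are clamped to 0 nM with a warning.

* **The F/F₀ pseudo-ratio**: division by the diastolic fluorescence $F_0$,
  obtained by averaging a user-flanked diastolic region
  (`define_f0()`). $F_0$ can be shared across all treatments of an
  experiment or re-defined per treatment; both paths are exposed.

## Level measurement

Diastolic and systolic levels are cursor readings in origin: the user
aligns one horizontal cursor with the flat diastolic segment and the other
with the transient peak, and the amplitude is their difference.
`measure_levels_manual()` stores such cursor values verbatim.
`measure_levels_auto()` automates the placement for batch work: the
diastolic level is the **mean** over a baseline window (a cursor aligned
with a flat region estimates its average), the systolic level is the
**maximum** over a peak window (the cursor touches the extremum). A peak
window whose maximum falls below the diastolic mean — possible when a noisy
baseline meets a mis-placed window — flags the result rather than failing,
since the batch should continue.

With noise of standard deviation $\sigma$, the max-based systolic estimate
is biased upward by a few $\sigma$ depending on window length; tests
therefore use windows of ~20 samples and noise at 1–2% of the amplitude,
where the bias is well inside a 10% amplitude tolerance.

## Decay regression

The decay phase is fitted by least squares with one of two models on
elapsed time $t$ from the window start:

$$Y = Y_0 + A e^{-kt} \qquad\text{(single)}$$
$$Y = Y_0 + A_1 e^{-k_1 t} + A_2 e^{-k_2 t} \qquad\text{(double)}$$

Rate constants are per millisecond throughout (a typical myocyte decay rate
is $k \approx 0.003\,\mathrm{ms^{-1}}$, i.e. $\tau \approx 300$ ms). Time
units are configurable at import (`time_units = "s"` converts), never
guessed from the data.

### Initial parameter prediction

A bounded-iteration optimizer needs a starting point near the optimum. The
package derives it from the same cursor gestures a user would make:

* $Y_0$ = the baseline cursor level; $A$ = peak cursor − baseline cursor.
* $k = 1/\tau$, with $\tau$ read directly off the experimental curve as the
  time at which the signal first falls below
  $Y_0 + (Y_{peak}-Y_0)/e$ ("smart" rate prediction). If the curve never
  crosses that level inside the window, $\tau$ falls back to half the
  window duration and the guess is flagged. With smart prediction disabled
  the initial $k$ is $1/(\text{window duration}/5)$.
* The five-parameter start is derived from the three-parameter one by user
  constants: $A_1 = A/a$, $A_2 = A/b$, $k_1 = k/c$, $k_2 = k/d$. The
  defaults $(a, b, c, d) = (2, 2, 0.5, 2)$ split the amplitude evenly and
  start one component twice as fast and one half as fast as the
  single-model rate. The published description of these constants is a bare
  multiplication-style typography; we read them as divisors, which is the
  reading consistent with "user defined constants" partitioning a
  single-model estimate, and keep all four configurable so the
  multiplicative reading is reachable as well.

### Optimization

Minimization uses the Levenberg–Marquardt routine of **minpack.lm**
(`nls.lm`), capped at 1000 iterations with parameter and function tolerance
$10^{-10}$. Rate constants are bounded below at $10^{-12}\,\mathrm{ms^{-1}}$
— a decay model must not wander into growth solutions — while amplitudes are
unconstrained in sign so inverted signals fit naturally. Optimizer failure
never raises: the result carries `converged = FALSE` with the initial guess
echoed, so batch runs degrade gracefully. On double fits the components are
re-ordered fast-first ($k_1 \ge k_2$) before reporting; the model is
symmetric in its components, so the ordering is a reporting convention.

The exponent sign deserves a note: we write both models with $e^{-kt}$ and
positive $k$. Any printed form without the minus sign describes the same
decay only under negative rate constants, which contradicts the positive
magnitudes conventionally reported; the negative-exponent form with
positive rates is the only self-consistent reading.

"**Zero fit range**" subtracts the baseline-cursor level from the window
before fitting, so the optimizer starts with $Y_0 \approx 0$. This is purely
a conditioning aid — the fitted rate agrees with the un-zeroed fit to well
below $10^{-6}$ relative — and the reported $Y_0$ is re-offset back to
original units.

### Goodness of fit and model comparison

For each fit, $SS_{reg} = \sum (Y - Y_{pred})^2$ and
$SS_{total} = \sum (Y - \bar{Y})^2$ give
$$R^2 = 1 - \frac{SS_{reg}}{SS_{total}}, \qquad
R^2_{adj} = 1 - \frac{SS_{reg}/(n-p)}{SS_{total}/(n-1)},$$
with $p = 3$ (single) or $5$ (double). A constant window
($SS_{total} = 0$) leaves $R^2$ undefined; the result is flagged rather
than erroring. For $n \sim 10^3$ the adjustment is negligible against the
unexplained variance, which the suite checks as an asymptotic property.

`fit_simultaneous()` runs both models on the *identical* window, making the
adjusted $R^2$ values directly comparable, and `indicate_best_fit()` picks
the larger one, breaking ties (difference below $10^{-12}$) toward the
single model by parsimony.

**A known statistical limitation.** Comparing nested least-squares models
by adjusted $R^2$ is equivalent to a fixed, lenient threshold on the
residual-sum reduction: the double model wins whenever its two extra
parameters capture more than about two noise variances of in-sample gain.
For data that are truly monoexponential that gain behaves like a
$\sigma^2\chi^2_2$ variable, so even an ideal optimizer would prefer the
double model in up to $P(\chi^2_2 > 2) \approx 37\%$ of windows; in
practice we measure an 16–20% false-double rate, stable across noise levels
(0.2%–10% of amplitude) and window lengths (800–1500 samples). This is a
property of the criterion, not of the optimizer. Data that are strongly
biexponential ($k_1/k_2 \ge 10$) are identified essentially always. Users
who need a stricter specificity should treat a "double" verdict with a
small adjusted-$R^2$ margin with caution; stricter criteria (F-test, AIC)
are deliberately out of scope, as adjusted $R^2$ is the comparison this
workflow is defined around.

## The synthetic-transient generator

`transient_spec()` + `make_transient()` generate the fixtures every stage
is tested on. The waveform holds the diastolic baseline for `onset` ms
(default 50 — real digitized records always include a pre-stimulus
stretch, and F0 definition needs one), rises along a saturating
exponential with `upstroke_tau` = 10 ms, peaks at `onset + 5*upstroke_tau`
— the upstroke is normalized so the peak sample equals
`baseline + amplitude` *exactly*, keeping noiseless recovery free of
truncation error — and then decays mono- or bi-exponentially with exactly
the model the regression stage fits. Defaults describe an F/F₀-scale
myocyte transient (baseline 1.0, amplitude 0.5, $k = 0.0033$ ms⁻¹, 1 ms
sampling, 1.5 s duration), matching the magnitudes of published
single-exponential myocyte fits; the double-exponential test scales
($k_1 = 0.017$, $k_2 = 0.0012$ ms⁻¹) likewise follow published fits.
`make_ratiometric_pair()` wraps the waveform into nominator/denominator
channels with per-channel backgrounds so the ratio path can be tested by
inverse construction.

Noise is additive, white and Gaussian — the simplest model consistent with
photomultiplier/photodiode recordings. The `"poor_snr"` preset sets the
noise to 10% of the amplitude, emulating a low signal-to-noise recording.
What the generator does **not** emulate: photon shot noise (variance
scaling with signal), photobleaching drift, motion artifacts, dye
compartmentalization, or multi-beat trains with alternans. Passing tests
therefore demonstrate correctness of the algorithms under the stated noise
model, not robustness to every artifact of real recordings.

## Problem sizes and determinism

The test suite and the acceptance script size their simulations to run in
seconds on one core while keeping estimator variance informative: windows
of 50–3000 samples, 100-run recovery studies, and 50-fixture-per-arm model
selection studies. All randomness flows through per-run integer seeds
(`transient_spec(seed = )` or an explicit seed to the helper RNG), so every
reported number is bit-reproducible; generation restores the caller's RNG
state afterwards.

## Degenerate inputs and edge policies

* Traces must be uniformly sampled within 1 part in 10⁴ relative jitter;
  irregular traces are rejected, never silently resampled.
* Fit windows need ≥ 6 samples (the 5-parameter model plus one), single
  fits ≥ 4.
* A window of constant values fits exactly with undefined $R^2$, flagged.
* Saturated calibration samples abort; sub-zero samples clamp with warning.
* Collation keeps one row per treatment label; the latest non-missing
  value of each column wins, so level and fit records sent separately merge
  and re-analysis overwrites.

## A worked example

```{r example, fig.width = 6, fig.height = 4}
spec <- transient_spec(noise_preset = "poor_snr", seed = 11)
tr <- make_transient(spec)
dw <- decay_window_spec(spec)
fits <- fit_decay(tr, dw$region, dw$y0_cursor, dw$peak_cursor, model = "both")
glance(fits$single)
glance(fits$double)
fits$best
plot_fit_comparison(fits)
```
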