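# catransient

Analysis of intracellular calcium transients recorded with fluorescent
indicators: raw-signal preparation, absolute-level measurement, and
multi-exponential decay kinetics by nonlinear least-squares regression with
nested-model comparison.

## Who this is for

Cardiac and cellular physiologists who record Ca transients (fura-2,
fluo-3, or any single- or dual-wavelength indicator) as digitized
time-series and need to turn raw fluorescence into physiological numbers:
diastolic and systolic Ca, transient amplitude, and the rate constant(s) of
the decay. The package replaces spreadsheet-and-cursor analysis with a
scriptable, reproducible pipeline; any decaying biological signal can be
analyzed the same way by skipping the calibration steps.

## What it computes

**Preparation.** All algorithms first subtract background fluorescence
(field of view without the cell), so every formula uses the
background-subtracted fluorescence *F*. Then, per indicator type:

- ratio of a dual-wavelength pair: `R = F_nom / F_denom`
- calibration to absolute calcium: `[Ca] = F·Kd / (Fmax − F)`
- pseudo-ratio normalization: `F/F0`, with `F0` the mean of a flanked
  diastolic region

**Levels.** Diastolic (mean of a baseline window), systolic (max of a peak
window), amplitude (difference) — the programmatic equivalent of aligning
Y-axis cursors with the resting segment and the peak.

**Decay kinetics.** Least-squares fits of

    Y = Y0 + A·exp(−k·t)                          (single, 3 parameters)
    Y = Y0 + A1·exp(−k1·t) + A2·exp(−k2·t)        (double, 5 parameters)

on a flanked decay window, with initial guesses derived from the cursor
levels and the curve's own time constant (`k = 1/τ`, τ read at the 1/e
level). Goodness of fit is reported as `R² = 1 − SSreg/SStotal` and the
parameter-count-adjusted `R²adj = 1 − (SSreg/(n−p))/(SStotal/(n−1))`, which
makes the two nested models directly comparable; `indicate_best_fit()`
selects the model with the larger adjusted R². Rate constants are per
millisecond.

A seedable synthetic-transient generator (`transient_spec()`,
`make_transient()`, `make_ratiometric_pair()`) provides ground-truth
fixtures, and `run_pipeline()` drives whole batches from a YAML config into
a collated one-row-per-treatment CSV.

## Worked example

```r
library(catransient)

spec <- transient_spec(noise_sd = 0.01, seed = 42)   # known ground truth:
tr   <- make_transient(spec)                         # baseline 1, amplitude 0.5,
dw   <- decay_window_spec(spec)                      # k = 0.0033 /ms

measure_levels_auto(tr, region(0, 40), region(80, 120), label = "control")
#> # A tibble: 1 × 5
#>   label   diastolic systolic amplitude flagged
#>   <chr>       <dbl>    <dbl>     <dbl> <lgl>
#> 1 control     1.000     1.51     0.514 FALSE

fits <- fit_decay(tr, dw$region, dw$y0_cursor, dw$peak_cursor, model = "both")
fits$single
#> <ca_fit> single exponential, 1401 points
#>         y0          a          k
#> 0.99960000 0.49949600 0.00329521
#>   SSreg = 0.136294  R² = 0.9938  adj R² = 0.9938
fits$best
#> [1] "single"
```

The measured amplitude (0.514) recovers the generating amplitude 0.5 to
within the noise-induced peak bias; the fitted rate constant 0.0033 /ms
matches the generating `k` to 0.1%, and the simultaneous double fit offers
no adjusted-R² improvement, so the single model is indicated — correctly,
since the fixture decays monoexponentially. `tidy()` and `glance()` return
the parameters and fit statistics as tibbles; `autoplot()` and
`plot_fit_comparison()` draw the fits over the data with the τ marker.

A command-line interface wrapping the same functions (subcommands
`simulate`, `prepare`, `measure`, `fit`, `collate`, `run`) is installed at:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "ca-analysis.R", package = "catransient"))') --help
```

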