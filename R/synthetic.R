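#' Specification of a synthetic calcium transient
#'
#' Parameterizes the generator used throughout the test suite: a diastolic
#' baseline, a fast saturating-exponential upstroke, and a mono- or
#' bi-exponential decay from the peak, with optional additive Gaussian white
#' noise and a background offset. The defaults describe an F/F0-scale
#' cardiac-myocyte transient: baseline 1.0, amplitude 0.5, decay rate
#' 0.0033/ms (tau roughly 300 ms), 10 ms upstroke time constant, 1 ms
#' sampling over 1.5 s — magnitudes typical of fluo-3 F/F0 recordings from
#' ventricular myocytes.
#'
#' @param baseline Diastolic signal level.
#' @param onset Stimulus onset time, ms: the trace holds the diastolic
#'   baseline for this long before the upstroke begins, giving level
#'   measurement and F0 definition a flankable resting segment.
#' @param amplitude Transient amplitude (peak minus baseline), `> 0`.
#' @param upstroke_tau Upstroke time constant, ms. The peak is placed at
#'   `onset + 5 * upstroke_tau`, with the upstroke normalized to reach
#'   `baseline + amplitude` exactly there, so the decay region is cleanly
#'   flankable and the generating parameters recover exactly from noiseless
#'   traces.
#' @param decay `"mono"` or `"bi"`.
#' @param k Mono-model decay rate constant, per ms.
#' @param a1_frac Bi model: fraction of the decay amplitude on the fast
#'   component, in (0, 1).
#' @param k1,k2 Bi-model rate constants, per ms, `k1 > k2`.
#' @param duration Recording length, ms (at least `10 * dt`).
#' @param dt Sampling interval, ms.
#' @param noise_sd Standard deviation of additive Gaussian noise, signal
#'   units. `noise_preset = "poor_snr"` sets it to 10% of the amplitude,
#'   emulating a recording with a relatively poor signal-to-noise ratio.
#' @param background Constant background fluorescence added to the signal.
#' @param seed Integer seed; the same spec always generates the identical
#'   trace.
#' @param label Treatment label for generated traces.
#' @param noise_preset Optional `"poor_snr"` shortcut (overrides
#'   `noise_sd`).
#' @return A `ca_transient_spec` list.
#' @examples
#' transient_spec()
#' transient_spec(decay = "bi", k1 = 0.017, k2 = 0.0012, a1_frac = 0.5)
#' @export
transient_spec <- function(baseline = 1, amplitude = 0.5, onset = 50,
                           upstroke_tau = 10,
                           decay = c("mono", "bi"), k = 0.0033,
                           a1_frac = 0.5, k1 = 0.017, k2 = 0.0012,
                           duration = 1500, dt = 1, noise_sd = 0,
                           background = 0, seed = 1L, label = "synthetic",
                           noise_preset = NULL) {
  decay <- match.arg(decay)
  if (!is.null(noise_preset)) {
    noise_preset <- match.arg(noise_preset, "poor_snr")
    noise_sd <- 0.10 * amplitude
  }
  stopifnot(dt > 0, duration >= 10 * dt, amplitude > 0, upstroke_tau > 0,
            onset >= 0, noise_sd >= 0)
  if (decay == "mono") {
    stopifnot(k > 0)
  } else {
    stopifnot(k1 > 0, k2 > 0, k1 > k2, a1_frac > 0, a1_frac < 1)
  }
  structure(list(baseline = baseline, amplitude = amplitude, onset = onset,
                 upstroke_tau = upstroke_tau, decay = decay, k = k,
                 a1_frac = a1_frac, k1 = k1, k2 = k2, duration = duration,
                 dt = dt, noise_sd = noise_sd, background = background,
                 seed = as.integer(seed), label = label),
            class = "ca_transient_spec")
}

#' Peak time of a synthetic transient
#'
#' The decay phase starts at `onset + 5 * upstroke_tau`; regions flanking
#' the decay for fitting should start at or after this time.
#'
#' @param spec A [transient_spec()].
#' @return Peak time in ms.
#' @export
peak_time <- function(spec) spec$onset + 5 * spec$upstroke_tau

# Noiseless signal without background: saturating-exponential upstroke,
# normalized so the peak sample equals baseline + amplitude exactly, then
# decay of the full amplitude. Exact peak attainment keeps the generated
# parameters recoverable without truncation error.
transient_waveform <- function(spec, t) {
  tp <- peak_time(spec)
  y <- numeric(length(t))
  rest <- t < spec$onset
  up <- !rest & t < tp
  y[rest] <- spec$baseline
  y[up] <- spec$baseline + spec$amplitude *
    (1 - exp(-(t[up] - spec$onset) / spec$upstroke_tau)) / (1 - exp(-5))
  td <- t[!rest & !up] - tp
  y[!rest & !up] <- if (spec$decay == "mono") {
    spec$baseline + spec$amplitude * exp(-spec$k * td)
  } else {
    spec$baseline + spec$amplitude * (spec$a1_frac * exp(-spec$k1 * td) +
                                      (1 - spec$a1_frac) * exp(-spec$k2 * td))
  }
  y
}

#' Generate a synthetic calcium transient
#'
#' Evaluates the spec's waveform on a uniform time grid, adds the constant
#' background and seeded Gaussian noise, and returns a raw trace. With
#' `noise_sd = 0` the decay segment satisfies the corresponding exponential
#' model exactly at every sample, so preparation and fitting can be checked
#' against known ground truth. The same spec (same seed) always produces a
#' bitwise-identical trace.
#'
#' @param spec A [transient_spec()].
#' @return A raw [ca_trace()].
#' @examples
#' tr <- make_transient(transient_spec(noise_sd = 0.01, seed = 42))
#' tr
#' @export
make_transient <- function(spec) {
  stopifnot(inherits(spec, "ca_transient_spec"))
  t <- seq(0, spec$duration, by = spec$dt)
  y <- transient_waveform(spec, t) + spec$background
  if (spec$noise_sd > 0) {
    y <- y + local_rnorm(spec$seed, length(t), sd = spec$noise_sd)
  }
  ca_trace(t, y, signal_kind = "raw", label = spec$label)
}

#' Generate a synthetic ratiometric channel pair
#'
#' Builds nominator and denominator channels whose background-subtracted
#' ratio reproduces the spec's waveform: the nominator is the waveform
#' scaled by a steady denominator level plus its background, the
#' denominator is that steady level plus its background. With
#' `spec$noise_sd = 0` the recovery through [ratio_traces()] is exact;
#' with noise, per-channel Gaussian noise of sd `spec$noise_sd` (times the
#' denominator level for the nominator channel) is added.
#'
#' @param spec A [transient_spec()] describing the ratio waveform.
#' @param denom_level Steady denominator fluorescence, `> 0`.
#' @param bg_nom,bg_denom Channel backgrounds added to the generated
#'   signals.
#' @return A list with raw traces `nominator` and `denominator`.
#' @export
make_ratiometric_pair <- function(spec, denom_level = 100, bg_nom = 0,
                                  bg_denom = 0) {
  stopifnot(inherits(spec, "ca_transient_spec"))
  if (denom_level <= 0) stop("denom_level must be > 0", call. = FALSE)
  t <- seq(0, spec$duration, by = spec$dt)
  waveform <- transient_waveform(spec, t)
  nom <- waveform * denom_level + bg_nom
  den <- rep(denom_level, length(t)) + bg_denom
  if (spec$noise_sd > 0) {
    nom <- nom + local_rnorm(spec$seed, length(t), sd = spec$noise_sd * denom_level)
    den <- den + local_rnorm(spec$seed + 1L, length(t), sd = spec$noise_sd * denom_level / 4)
  }
  list(nominator = ca_trace(t, nom, label = paste0(spec$label, "_nom")),
       denominator = ca_trace(t, den, label = paste0(spec$label, "_denom")))
}

# Seeded draws that do not disturb the caller's RNG state.
local_rnorm <- function(seed, n, sd) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  stats::rnorm(n, sd = sd)
}

#' Decay region and cursor levels implied by a spec
#'
#' Helper for analyses of generated transients: the region flanking the
#' decay phase (from the peak to the end of the recording) and the
#' noiseless baseline/peak cursor levels, in the generated trace's units
#' (background included).
#'
#' @param spec A [transient_spec()].
#' @param skip_ms Milliseconds after the peak to skip before the window
#'   starts (default 0).
#' @return A list with `region`, `y0_cursor`, `peak_cursor`.
#' @export
decay_window_spec <- function(spec, skip_ms = 0) {
  tp <- peak_time(spec)
  y_peak <- spec$background + spec$baseline + spec$amplitude
  list(region = region(tp + skip_ms, spec$duration),
       y0_cursor = spec$background + spec$baseline,
       peak_cursor = y_peak)
}
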