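#' Subtract background fluorescence
#'
#' Raw fluorescence is collected from the whole optical field, so the
#' fluorescence of the field with the cell absent must be removed before any
#' further preparation. Every downstream preparation ([ratio_traces()],
#' [calibrate_ca()], [normalize_f0()]) requires the input to be
#' background-subtracted, and subtraction is applied exactly once: a trace
#' that is already past the raw stage is rejected.
#'
#' @param trace A raw [ca_trace()].
#' @param f_background Background fluorescence: a non-negative scalar, or a
#'   background recording (trace or numeric vector) reduced to its mean.
#' @return The trace with every value decreased by `f_background` and
#'   `signal_kind = "background_subtracted"`.
#' @examples
#' tr <- ca_trace(0:3, c(5, 6, 7, 6))
#' subtract_background(tr, 2)
#' @export
subtract_background <- function(trace, f_background) {
  trace <- assert_trace(trace)
  if (signal_kind(trace) != "raw") {
    stop("background subtraction applies to raw traces only (got signal_kind = \"",
         signal_kind(trace), "\"); it is performed exactly once", call. = FALSE)
  }
  bg <- reduce_background(f_background)
  if (bg < 0) stop("f_background must be >= 0, got ", bg, call. = FALSE)
  retrace(trace, value = trace$value - bg,
          signal_kind = "background_subtracted")
}

#' Ratio a ratiometric indicator pair
#'
#' Dual-wavelength indicators such as fura-2 yield a nominator and a
#' denominator signal; their per-sample ratio cancels dye-concentration
#' artifacts. Background subtraction is applied to each channel internally
#' before division, so the inputs are the raw channel recordings.
#'
#' @param nominator,denominator Raw [ca_trace()]s with identical time bases.
#' @param bg_nom,bg_denom Per-channel background fluorescence (scalar, or a
#'   recording reduced to its mean).
#' @param label Label for the resulting ratio trace; defaults to the
#'   nominator's label.
#' @return A trace of per-sample ratios with `signal_kind = "ratio"`.
#' @examples
#' t <- 0:3
#' ratio_traces(ca_trace(t, c(4, 6, 4, 6)), ca_trace(t, c(2, 3, 2, 3)))
#' @export
ratio_traces <- function(nominator, denominator, bg_nom = 0, bg_denom = 0,
                         label = trace_label(nominator)) {
  nominator <- assert_trace(nominator, "nominator")
  denominator <- assert_trace(denominator, "denominator")
  if (nrow(nominator) != nrow(denominator)) {
    stop("nominator and denominator lengths differ (", nrow(nominator),
         " vs ", nrow(denominator), ")", call. = FALSE)
  }
  if (max(abs(nominator$time - denominator$time)) > 1e-9 * max(abs(nominator$time), 1)) {
    stop("nominator and denominator time bases do not match", call. = FALSE)
  }
  num <- subtract_background(nominator, bg_nom)
  den <- subtract_background(denominator, bg_denom)
  bad <- which(den$value <= 0)
  if (length(bad) > 0L) {
    stop("background-subtracted denominator is <= 0 at sample ", bad[1L],
         " (t = ", den$time[bad[1L]], " ms); ratio undefined", call. = FALSE)
  }
  ca_trace(num$time, num$value / den$value, signal_kind = "ratio",
           label = label)
}

#' Calibrate a non-ratiometric signal to absolute calcium concentration
#'
#' Converts background-subtracted fluorescence F to intracellular calcium
#' concentration through the indicator's binding curve,
#' \deqn{[Ca] = \frac{F \times K_d}{F_{max} - F}}{[Ca] = F * Kd / (Fmax - F)}
#' where `kd` is the indicator's dissociation constant and `f_max` its
#' fluorescence at saturating calcium. The conversion is strictly increasing
#' in F on (0, f_max). Samples at or above `f_max` abort the calibration:
#' the formula diverges there and negative concentrations must not propagate
#' silently. Samples at or below zero are clamped to 0 nM with a warning and
#' a `clamped` attribute on the result.
#'
#' @param trace A background-subtracted [ca_trace()].
#' @param kd Dissociation constant, nM, `> 0`.
#' @param f_max Maximal fluorescence, `> 0`.
#' @return A trace in nM with `signal_kind = "calcium_nM"`.
#' @examples
#' tr <- ca_trace(0:2, c(2, 5, 8), signal_kind = "background_subtracted")
#' calibrate_ca(tr, kd = 400, f_max = 10)
#' @export
calibrate_ca <- function(trace, kd, f_max) {
  trace <- assert_trace(trace)
  if (signal_kind(trace) != "background_subtracted") {
    stop("calibrate_ca requires a background-subtracted trace (got \"",
         signal_kind(trace), "\"); subtract background first", call. = FALSE)
  }
  if (is.null(kd) || is.null(f_max)) {
    stop("calibration to [Ca] requires both kd and f_max", call. = FALSE)
  }
  if (kd <= 0) stop("kd must be > 0, got ", kd, call. = FALSE)
  if (f_max <= 0) stop("f_max must be > 0, got ", f_max, call. = FALSE)
  f <- trace$value
  sat <- which(f >= f_max)
  if (length(sat) > 0L) {
    stop("fluorescence reaches f_max at sample ", sat[1L], " (F = ",
         f[sat[1L]], " >= f_max = ", f_max,
         "); indicator saturated, calibration undefined", call. = FALSE)
  }
  clamped <- f <= 0
  if (any(clamped)) {
    warning(sum(clamped), " sample(s) with F <= 0 clamped to 0 nM",
            call. = FALSE)
    f[clamped] <- 0
  }
  out <- retrace(trace, value = (f * kd) / (f_max - f),
                 signal_kind = "calcium_nM")
  attr(out, "clamped") <- any(clamped)
  out
}

#' Average a flanked region to define F0
#'
#' F0 is the diastolic (resting) fluorescence used as the denominator of the
#' F/F0 pseudo-ratio. The user flanks a diastolic segment of the transient;
#' this function returns the arithmetic mean of the samples inside it.
#'
#' @param trace A [ca_trace()].
#' @param reg A [region()] (or length-2 numeric) within the trace span,
#'   containing at least one sample.
#' @return Scalar mean of the in-region values.
#' @examples
#' tr <- ca_trace(0:9, c(rep(1, 5), 1.5, 1.4, 1.3, 1.2, 1.1))
#' define_f0(tr, region(0, 4))
#' @export
define_f0 <- function(trace, reg) {
  trace <- assert_trace(trace)
  idx <- region_index(trace, reg, what = "F0 region")
  mean(trace$value[idx])
}

#' Convert to the F/F0 pseudo-ratio
#'
#' Normalizes a background-subtracted trace by the diastolic fluorescence
#' F0, yielding relative signal changes that reflect changes of calcium.
#' F0 may be shared across treatments or re-defined per treatment (pass a
#' different `f0` per call); [define_f0()] computes it from a flanked
#' diastolic region.
#'
#' @param trace A background-subtracted [ca_trace()].
#' @param f0 Diastolic fluorescence, `> 0`.
#' @return A trace with `signal_kind = "f_over_f0"`.
#' @examples
#' tr <- ca_trace(0:2, c(2, 4, 3), signal_kind = "background_subtracted")
#' normalize_f0(tr, f0 = 2)
#' @export
normalize_f0 <- function(trace, f0) {
  trace <- assert_trace(trace)
  if (signal_kind(trace) != "background_subtracted") {
    stop("normalize_f0 requires a background-subtracted trace (got \"",
         signal_kind(trace), "\"); subtract background first", call. = FALSE)
  }
  if (!is.numeric(f0) || length(f0) != 1L || !is.finite(f0) || f0 <= 0) {
    stop("f0 must be a positive finite scalar", call. = FALSE)
  }
  retrace(trace, value = trace$value / f0, signal_kind = "f_over_f0")
}

#' Prepare a raw trace in one step
#'
#' Convenience wrapper chaining background subtraction with the chosen
#' conversion. `kind = "background"` stops after subtraction; `"calcium"`
#' applies [calibrate_ca()]; `"f_over_f0"` applies [normalize_f0()] (with
#' `f0` taken from `constants`, or defined from `f0_region` on the
#' background-subtracted trace when `constants$f0` is absent).
#'
#' @param trace A raw [ca_trace()].
#' @param kind One of `"background"`, `"calcium"`, `"f_over_f0"`.
#' @param constants A [calibration_constants()] object.
#' @param f0_region Optional [region()] used to define F0 per-treatment when
#'   `constants$f0` is `NULL`.
#' @return A prepared [ca_trace()].
#' @export
prepare_trace <- function(trace, kind = c("background", "calcium", "f_over_f0"),
                          constants = calibration_constants(),
                          f0_region = NULL) {
  kind <- match.arg(kind)
  sub <- subtract_background(trace, constants$f_background)
  switch(kind,
    background = sub,
    calcium = {
      if (is.null(constants$kd) || is.null(constants$f_max)) {
        stop("calibration to [Ca] requires constants kd and f_max; missing: ",
             paste(c("kd", "f_max")[c(is.null(constants$kd), is.null(constants$f_max))],
                   collapse = ", "), call. = FALSE)
      }
      calibrate_ca(sub, kd = constants$kd, f_max = constants$f_max)
    },
    f_over_f0 = {
      f0 <- constants$f0
      if (is.null(f0)) {
        if (is.null(f0_region)) {
          stop("F/F0 preparation needs constants$f0 or an f0_region", call. = FALSE)
        }
        f0 <- define_f0(sub, f0_region)
      }
      normalize_f0(sub, f0)
    })
}
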