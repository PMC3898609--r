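#' Record manually cursor-placed diastolic and systolic levels
#'
#' Faithful emulation of on-screen Y-axis cursor measurement: the user reads
#' the diastolic level off the flat resting segment and the systolic level
#' off the transient's peak, and the amplitude is their difference. The two
#' levels are stored verbatim.
#'
#' @param trace A prepared [ca_trace()] (carried for its label and units;
#'   the levels themselves are taken as given).
#' @param diastolic_level,systolic_level Cursor levels in the trace's signal
#'   units, `systolic_level >= diastolic_level`.
#' @param label Treatment label; defaults to the trace's.
#' @return A one-row `ca_levels` tibble with columns `label`, `diastolic`,
#'   `systolic`, `amplitude`, `flagged`.
#' @examples
#' tr <- ca_trace(0:9, rep(1, 10), signal_kind = "calcium_nM")
#' measure_levels_manual(tr, 100, 350)
#' @export
measure_levels_manual <- function(trace, diastolic_level, systolic_level,
                                  label = trace_label(trace)) {
  trace <- assert_trace(trace)
  if (!is.finite(diastolic_level) || !is.finite(systolic_level)) {
    stop("levels must be finite", call. = FALSE)
  }
  if (systolic_level < diastolic_level) {
    stop("systolic level (", systolic_level, ") below diastolic level (",
         diastolic_level, "); cursors inverted", call. = FALSE)
  }
  new_ca_levels(label, diastolic_level, systolic_level, flagged = FALSE)
}

#' Measure diastolic, systolic and amplitude from regions
#'
#' Batch counterpart of cursor placement: the diastolic level is the mean of
#' the values in a flat baseline window (one cursor aligned with the
#' diastolic region), the systolic level is the maximum inside a peak window
#' (the other cursor aligned with the transient's peak), and the amplitude
#' is their difference. A peak window whose maximum falls below the baseline
#' mean — possible with noisy baselines and a mis-chosen window — yields a
#' flagged result rather than an error.
#'
#' @param trace A prepared [ca_trace()].
#' @param baseline_region,peak_region [region()]s within the trace, each
#'   containing at least one sample.
#' @param label Treatment label; defaults to the trace's.
#' @return A one-row `ca_levels` tibble (see [measure_levels_manual()]).
#' @examples
#' tr <- ca_trace(0:9, c(rep(1, 5), 1.5, 1.4, 1.3, 1.2, 1.1))
#' measure_levels_auto(tr, region(0, 4), region(5, 9))
#' @export
measure_levels_auto <- function(trace, baseline_region, peak_region,
                                label = trace_label(trace)) {
  trace <- assert_trace(trace)
  dia <- mean(trace$value[region_index(trace, baseline_region, "baseline region")])
  sys <- max(trace$value[region_index(trace, peak_region, "peak region")])
  flagged <- sys < dia
  if (flagged) {
    warning("peak-window maximum (", signif(sys, 6),
            ") below diastolic mean (", signif(dia, 6),
            "); check region placement", call. = FALSE)
  }
  new_ca_levels(label, dia, sys, flagged = flagged)
}

# amplitude == systolic - diastolic is asserted at construction
new_ca_levels <- function(label, diastolic, systolic, flagged = FALSE) {
  out <- tibble::tibble(label = as.character(label),
                        diastolic = as.numeric(diastolic),
                        systolic = as.numeric(systolic),
                        amplitude = as.numeric(systolic) - as.numeric(diastolic),
                        flagged = isTRUE(flagged))
  stopifnot(out$amplitude == out$systolic - out$diastolic)
  class(out) <- c("ca_levels", class(out))
  out
}
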