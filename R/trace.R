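#' Construct a calcium-transient trace
#'
#' A trace is a uniformly sampled fluorescence (or derived) time series,
#' stored as a tibble with columns `time` (milliseconds) and `value`, plus
#' attributes recording what kind of signal the values represent and a
#' free-text treatment label. All preparation and analysis functions in the
#' package take and return this form, so calls chain with the pipe.
#'
#' @param time Numeric vector of sample times in milliseconds. Must be
#'   strictly increasing and uniformly spaced (relative jitter below
#'   1 part in 1e4); irregular traces are rejected rather than resampled.
#' @param value Numeric vector of signal values, same length as `time`.
#' @param signal_kind One of `"raw"`, `"background_subtracted"`, `"ratio"`,
#'   `"f_over_f0"`, `"calcium_nM"`. Preparation functions enforce the
#'   allowed transitions (raw signals must be background-subtracted before
#'   any conversion).
#' @param label Treatment label, free text.
#' @return A `ca_trace` tibble with columns `time` and `value`.
#' @examples
#' tr <- ca_trace(0:99, 1 + 0.5 * exp(-0.01 * (0:99)))
#' tr
#' @export
ca_trace <- function(time, value, signal_kind = "raw", label = "") {
  time <- as.numeric(time)
  value <- as.numeric(value)
  if (length(time) != length(value)) {
    stop("`time` and `value` must have equal length, got ",
         length(time), " and ", length(value), call. = FALSE)
  }
  if (length(time) < 2L) {
    stop("a trace needs at least 2 samples, got ", length(time), call. = FALSE)
  }
  if (anyNA(time) || anyNA(value)) {
    stop("trace contains missing values", call. = FALSE)
  }
  dt <- diff(time)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1L] + 1L
    stop("time must be strictly increasing; violation at sample ", bad,
         " (t = ", time[bad], ")", call. = FALSE)
  }
  # digitizer output is assumed: reject irregular sampling instead of resampling
  if ((max(dt) - min(dt)) / mean(dt) > 1e-4) {
    stop("trace is not uniformly sampled (relative jitter exceeds 1e-4); ",
         "resample before analysis", call. = FALSE)
  }
  signal_kind <- match.arg(signal_kind, ca_signal_kinds())
  out <- tibble::tibble(time = time, value = value)
  attr(out, "signal_kind") <- signal_kind
  attr(out, "label") <- as.character(label)
  class(out) <- c("ca_trace", class(out))
  out
}

ca_signal_kinds <- function() {
  c("raw", "background_subtracted", "ratio", "f_over_f0", "calcium_nM")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("<ca_trace> %d samples, dt = %g ms, signal = %s%s\n",
              nrow(x), stats::median(diff(x$time)), signal_kind(x),
              if (nzchar(trace_label(x))) paste0(", label = \"", trace_label(x), "\"") else ""))
  NextMethod()
}

#' Signal kind and label accessors
#'
#' @param trace A [ca_trace()].
#' @return `signal_kind()` returns the preparation state of the trace;
#'   `trace_label()` its treatment label.
#' @export
signal_kind <- function(trace) {
  attr(trace, "signal_kind") %||% "raw"
}

#' @rdname signal_kind
#' @export
trace_label <- function(trace) {
  attr(trace, "label") %||% ""
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rebuild a trace with new values and/or metadata, keeping the time base.
retrace <- function(trace, value = trace$value, signal_kind = signal_kind(trace),
                    label = trace_label(trace)) {
  ca_trace(trace$time, value, signal_kind = signal_kind, label = label)
}

assert_trace <- function(trace, arg = "trace") {
  if (!inherits(trace, "ca_trace")) {
    if (is.data.frame(trace) && all(c("time", "value") %in% names(trace))) {
      return(ca_trace(trace$time, trace$value))
    }
    stop("`", arg, "` must be a ca_trace (or a data frame with time/value columns)",
         call. = FALSE)
  }
  trace
}

#' Define a time region on a trace
#'
#' Regions are the programmatic counterpart of the X-axis cursors used to
#' flank a segment of a plotted transient: a contiguous `[t_start, t_end]`
#' window, used to define the F0 averaging segment, the baseline and peak
#' windows for level measurement, and the decay window for regression.
#'
#' @param t_start,t_end Window bounds in milliseconds, `t_start < t_end`.
#' @return A `ca_region` object.
#' @examples
#' region(100, 400)
#' @export
region <- function(t_start, t_end) {
  t_start <- as.numeric(t_start)[1L]
  t_end <- as.numeric(t_end)[1L]
  if (!is.finite(t_start) || !is.finite(t_end) || t_start >= t_end) {
    stop("region requires finite t_start < t_end, got [", t_start, ", ",
         t_end, "]", call. = FALSE)
  }
  structure(list(t_start = t_start, t_end = t_end), class = "ca_region")
}

#' @export
print.ca_region <- function(x, ...) {
  cat(sprintf("<ca_region> [%g, %g] ms\n", x$t_start, x$t_end))
  invisible(x)
}

as_region <- function(x) {
  if (inherits(x, "ca_region")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(region(x[1L], x[2L]))
  stop("expected a region() or a length-2 numeric [t_start, t_end]", call. = FALSE)
}

# Indices of trace samples falling inside a region (inclusive bounds).
region_index <- function(trace, reg, what = "region") {
  reg <- as_region(reg)
  span <- range(trace$time)
  if (reg$t_start < span[1L] - 1e-9 || reg$t_end > span[2L] + 1e-9) {
    stop(what, " [", reg$t_start, ", ", reg$t_end,
         "] falls outside the trace span [", span[1L], ", ", span[2L], "]",
         call. = FALSE)
  }
  idx <- which(trace$time >= reg$t_start & trace$time <= reg$t_end)
  if (length(idx) == 0L) {
    stop(what, " contains no samples", call. = FALSE)
  }
  idx
}

#' Calibration constants for signal preparation
#'
#' Bundles the scalar constants used by the preparation stage: background
#' fluorescence (field of view with the cell absent, subtracted from every
#' raw signal), the indicator's maximal fluorescence `f_max` and dissociation
#' constant `kd` (both required for calibration to absolute \[Ca\]), and the
#' diastolic fluorescence `f0` (required for the F/F0 pseudo-ratio).
#'
#' @param f_background Background fluorescence, `>= 0`. May also be a
#'   background trace or numeric vector, which is reduced to its mean.
#' @param f_max Maximal indicator fluorescence at saturating calcium, `> 0`
#'   (optional, needed for \[Ca\] calibration).
#' @param kd Indicator dissociation constant in nM, `> 0` (optional, needed
#'   for \[Ca\] calibration).
#' @param f0 Diastolic fluorescence, `> 0` (optional, needed for F/F0).
#' @return A `ca_calibration` list.
#' @examples
#' calibration_constants(f_background = 12, f_max = 250, kd = 400)
#' @export
calibration_constants <- function(f_background = 0, f_max = NULL, kd = NULL,
                                  f0 = NULL) {
  f_background <- reduce_background(f_background)
  if (f_background < 0) stop("f_background must be >= 0", call. = FALSE)
  if (!is.null(f_max) && f_max <= 0) stop("f_max must be > 0", call. = FALSE)
  if (!is.null(kd) && kd <= 0) stop("kd must be > 0", call. = FALSE)
  if (!is.null(f0) && f0 <= 0) stop("f0 must be > 0", call. = FALSE)
  structure(list(f_background = f_background, f_max = f_max, kd = kd, f0 = f0),
            class = "ca_calibration")
}

# A background recording is reduced to its mean: subtraction uses one steady
# scalar per channel.
reduce_background <- function(bg) {
  if (inherits(bg, "ca_trace") || is.data.frame(bg)) bg <- bg$value
  bg <- as.numeric(bg)
  if (anyNA(bg)) stop("background contains missing values", call. = FALSE)
  mean(bg)
}
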