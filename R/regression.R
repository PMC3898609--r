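#' Extract and re-zero a fit window from a trace
#'
#' Flanks the decay region to be fitted (the X-cursor surrogate) and
#' re-zeroes its time axis so the regression sees elapsed time from the
#' window start — the rate constant then never depends on the absolute
#' recording time. With `zero = TRUE` ("zero fit range") the baseline cursor
#' level is also subtracted from the values, so the fitted baseline starts
#' near 0; this conditions the optimizer and reduces iterations but does not
#' change the fitted rate. The offset is recorded so reported baselines are
#' re-offset back to original units.
#'
#' @param trace A prepared [ca_trace()].
#' @param reg [region()] with at least 6 samples (the window must exceed the
#'   5-parameter double model).
#' @param zero Apply the zero-fit-range offset?
#' @param y0_cursor Baseline cursor level, subtracted when `zero = TRUE`.
#' @return A `ca_fit_window` tibble with columns `t_rel` (ms from window
#'   start) and `y`, carrying the zero offset and source region as
#'   attributes.
#' @examples
#' tr <- ca_trace(0:99, 1 + 0.5 * exp(-0.01 * (0:99)))
#' extract_fit_window(tr, region(10, 90))
#' @export
extract_fit_window <- function(trace, reg, zero = FALSE, y0_cursor = 0) {
  trace <- assert_trace(trace)
  idx <- region_index(trace, reg, what = "fit region")
  if (length(idx) < 6L) {
    stop("fit region contains only ", length(idx),
         " samples; at least 6 are required (5-parameter double model)",
         call. = FALSE)
  }
  y <- trace$value[idx]
  offset <- 0
  if (isTRUE(zero)) {
    offset <- y0_cursor
    y <- y - offset
  }
  out <- tibble::tibble(t_rel = trace$time[idx] - trace$time[idx[1L]], y = y)
  attr(out, "zeroed") <- isTRUE(zero)
  attr(out, "offset") <- offset
  attr(out, "region") <- as_region(reg)
  attr(out, "label") <- trace_label(trace)
  class(out) <- c("ca_fit_window", class(out))
  out
}

as_fit_window <- function(window) {
  if (inherits(window, "ca_fit_window")) return(window)
  if (is.data.frame(window) && all(c("t_rel", "y") %in% names(window))) {
    out <- tibble::as_tibble(window[c("t_rel", "y")])
    attr(out, "zeroed") <- FALSE
    attr(out, "offset") <- 0
    class(out) <- c("ca_fit_window", class(out))
    return(out)
  }
  stop("expected a fit window from extract_fit_window() or a data frame ",
       "with t_rel/y columns", call. = FALSE)
}

window_offset <- function(window) attr(window, "offset") %||% 0

#' Estimate the decay time constant from the experimental curve
#'
#' The initial rate constant for the single-exponential fit is predicted
#' from the curve's time constant, k = 1/tau. Tau is read directly off the
#' experimental curve as the elapsed time from the window start until the
#' signal first falls below `y0 + (peak - y0)/e`, i.e. the 1/e level between
#' the two Y-cursors. If the curve never crosses that level inside the
#' window, half the window duration is returned as a flagged fallback.
#'
#' @param window A fit window from [extract_fit_window()].
#' @param y0_cursor,peak_cursor Baseline and peak Y-cursor levels, in the
#'   window's (possibly zeroed) units, `peak_cursor > y0_cursor`.
#' @return Tau in ms, with attribute `fallback = TRUE` when the 1/e level
#'   was never crossed.
#' @examples
#' w <- tibble::tibble(t_rel = 0:500, y = 1 + 0.5 * exp(-(0:500) / 100))
#' estimate_tau(w, 1, 1.5)
#' @export
estimate_tau <- function(window, y0_cursor, peak_cursor) {
  window <- as_fit_window(window)
  if (peak_cursor <= y0_cursor) {
    stop("peak cursor must lie above the baseline cursor (got peak = ",
         peak_cursor, ", baseline = ", y0_cursor, ")", call. = FALSE)
  }
  level <- y0_cursor + (peak_cursor - y0_cursor) / exp(1)
  below <- which(window$y < level)
  if (length(below) == 0L) {
    tau <- (max(window$t_rel) - min(window$t_rel)) / 2
    attr(tau, "fallback") <- TRUE
    return(tau)
  }
  tau <- window$t_rel[below[1L]]
  if (tau <= 0) tau <- window$t_rel[2L]  # crossing at the first sample
  attr(tau, "fallback") <- FALSE
  tau
}

#' Initial parameters for the single-exponential fit
#'
#' Builds the "first guess" from the cursor positions: the baseline cursor
#' gives Y0, the peak cursor minus Y0 gives the amplitude A, and the rate
#' constant k is 1/tau with tau predicted from the experimental curve
#' ([estimate_tau()], "smart RC prediction"). With prediction disabled the
#' initial k falls back to 1/(window duration / 5).
#'
#' @param window A fit window from [extract_fit_window()].
#' @param y0_cursor,peak_cursor Baseline and peak cursor levels,
#'   `peak_cursor > y0_cursor`.
#' @param smart_rc Use the tau-based rate-constant prediction? Default `TRUE`.
#' @return A `ca_guess` list with fields `y0`, `a`, `k`, `tau`.
#' @export
initial_guess_single <- function(window, y0_cursor, peak_cursor,
                                 smart_rc = TRUE) {
  window <- as_fit_window(window)
  if (peak_cursor <= y0_cursor) {
    stop("peak cursor must lie above the baseline cursor (got peak = ",
         peak_cursor, ", baseline = ", y0_cursor, ")", call. = FALSE)
  }
  if (isTRUE(smart_rc)) {
    tau <- estimate_tau(window, y0_cursor, peak_cursor)
  } else {
    tau <- (max(window$t_rel) - min(window$t_rel)) / 5
    attr(tau, "fallback") <- FALSE
  }
  structure(list(y0 = y0_cursor,
                 a = peak_cursor - y0_cursor,
                 k = 1 / as.numeric(tau),
                 tau = as.numeric(tau),
                 tau_fallback = isTRUE(attr(tau, "fallback")),
                 smart_rc = isTRUE(smart_rc)),
            class = "ca_guess")
}

#' Initial parameters for the double-exponential fit
#'
#' Derives the five-parameter starting point from a single-exponential guess
#' by dividing its amplitude and rate by user constants:
#' `a1 = a/a_div`, `a2 = a/b_div`, `k1 = k/c_div`, `k2 = k/d_div`.
#' The defaults (2, 2, 0.5, 2) split the amplitude evenly and start one
#' component twice as fast and one half as fast as the single-model rate.
#'
#' @param single A `ca_guess` from [initial_guess_single()].
#' @param a_div,b_div,c_div,d_div Positive user constants.
#' @return A `ca_guess` list extended with `a1`, `a2`, `k1`, `k2` and the
#'   divisors used.
#' @export
initial_guess_double <- function(single, a_div = 2, b_div = 2,
                                 c_div = 0.5, d_div = 2) {
  if (!inherits(single, "ca_guess")) {
    stop("`single` must come from initial_guess_single()", call. = FALSE)
  }
  divs <- c(a_div = a_div, b_div = b_div, c_div = c_div, d_div = d_div)
  if (any(!is.finite(divs)) || any(divs <= 0)) {
    stop("divisors must all be positive, got (",
         paste(divs, collapse = ", "), ")", call. = FALSE)
  }
  out <- single
  out$a1 <- single$a / a_div
  out$a2 <- single$a / b_div
  out$k1 <- single$k / c_div
  out$k2 <- single$k / d_div
  out$divisors <- as.list(divs)
  out
}

#' Goodness of fit: sums of squares, R-squared, adjusted R-squared
#'
#' \deqn{R^2 = 1 - SS_{reg}/SS_{total}}{R2 = 1 - SSreg/SStotal}
#' where SSreg is the sum of squared regression residuals and SStotal the
#' sum of squared deviations of the data from their mean. To compare fits
#' with different parameter counts on the same window,
#' \deqn{R^2_{adj} = 1 - \frac{SS_{reg}/(n-p)}{SS_{total}/(n-1)}}{
#'   adjR2 = 1 - (SSreg/(n-p)) / (SStotal/(n-1))}
#' penalizes by the number of parameters p. For n of order 10^3 the two
#' differ negligibly. A constant signal (SStotal = 0) leaves R-squared
#' undefined; the result is flagged rather than an error.
#'
#' @param y Observed values.
#' @param y_pred Predicted values, same length, with `length(y) > p`.
#' @param p Number of model parameters (3 for single, 5 for double).
#' @return A list with `ss_reg`, `ss_total`, `r_squared`,
#'   `adjusted_r_squared`, `undefined`.
#' @examples
#' goodness_of_fit(c(1, 2, 3, 4), c(1.1, 1.9, 3.0, 4.0), p = 3)
#' @export
goodness_of_fit <- function(y, y_pred, p) {
  n <- length(y)
  if (length(y_pred) != n) {
    stop("y and y_pred lengths differ (", n, " vs ", length(y_pred), ")",
         call. = FALSE)
  }
  if (n <= p) stop("need n > p, got n = ", n, ", p = ", p, call. = FALSE)
  ss_reg <- sum((y - y_pred)^2)
  ss_total <- sum((y - mean(y))^2)
  if (ss_total == 0) {
    return(list(ss_reg = ss_reg, ss_total = 0, r_squared = NA_real_,
                adjusted_r_squared = NA_real_, undefined = TRUE))
  }
  list(ss_reg = ss_reg,
       ss_total = ss_total,
       r_squared = 1 - ss_reg / ss_total,
       adjusted_r_squared = 1 - (ss_reg / (n - p)) / (ss_total / (n - 1)),
       undefined = FALSE)
}

# Model curves. Decay is written exp(-k t) with k constrained positive.
predict_single <- function(par, t) par[["y0"]] + par[["a"]] * exp(-par[["k"]] * t)
predict_double <- function(par, t) {
  par[["y0"]] +
    par[["a1"]] * exp(-par[["k1"]] * t) +
    par[["a2"]] * exp(-par[["k2"]] * t)
}

#' Fit a single-exponential decay
#'
#' Minimizes the sum of squared residuals of
#' \deqn{Y_{pred} = Y_0 + A e^{-kt}}{Ypred = Y0 + A exp(-k t)}
#' over (Y0, A, k) by Levenberg–Marquardt least squares, starting from the
#' cursor-derived initial guess. Rate constants are constrained positive
#' (a decay, not growth); amplitudes are unconstrained in sign so inverted
#' signals fit too. If the window was zeroed, the reported Y0 has the cursor
#' offset added back so all parameters are in original signal units.
#' Optimizer failure never raises: the result carries `converged = FALSE`
#' with the initial guess echoed.
#'
#' @param window A fit window from [extract_fit_window()] (at least 4
#'   samples for the 3-parameter model).
#' @param init A `ca_guess` from [initial_guess_single()].
#' @param max_iterations Iteration cap for the least-squares loop.
#' @param tolerance Parameter tolerance for convergence.
#' @return A `ca_fit` object; see [tidy.ca_fit()], [glance.ca_fit()],
#'   [autoplot.ca_fit()].
#' @examples
#' w <- tibble::tibble(t_rel = 0:200, y = 1 + 0.5 * exp(-0.01 * (0:200)))
#' fit_single(w, initial_guess_single(w, 1, 1.5))
#' @export
fit_single <- function(window, init, max_iterations = 1000, tolerance = 1e-10) {
  window <- as_fit_window(window)
  if (nrow(window) < 4L) {
    stop("single-exponential fit needs at least 4 samples, got ",
         nrow(window), call. = FALSE)
  }
  start <- c(y0 = init$y0, a = init$a, k = init$k)
  run_fit(window, start, model = "single", init = init,
          lower = c(-Inf, -Inf, 1e-12),
          max_iterations = max_iterations, tolerance = tolerance)
}

#' Fit a double-exponential decay
#'
#' Minimizes the sum of squared residuals of
#' \deqn{Y_{pred} = Y_0 + A_1 e^{-k_1 t} + A_2 e^{-k_2 t}}{
#'   Ypred = Y0 + A1 exp(-k1 t) + A2 exp(-k2 t)}
#' over the five parameters, starting from the divisor-derived guess of
#' [initial_guess_double()]. On output the components are sorted fast-first
#' (`k1 >= k2`). Conventions otherwise follow [fit_single()].
#'
#' @param window A fit window with at least 6 samples.
#' @param init A `ca_guess` from [initial_guess_double()].
#' @inheritParams fit_single
#' @return A `ca_fit` object.
#' @export
fit_double <- function(window, init, max_iterations = 1000, tolerance = 1e-10) {
  window <- as_fit_window(window)
  if (nrow(window) < 6L) {
    stop("double-exponential fit needs at least 6 samples, got ",
         nrow(window), call. = FALSE)
  }
  if (is.null(init$a1)) {
    stop("`init` lacks double-model fields; build it with initial_guess_double()",
         call. = FALSE)
  }
  start <- c(y0 = init$y0, a1 = init$a1, k1 = init$k1,
             a2 = init$a2, k2 = init$k2)
  run_fit(window, start, model = "double", init = init,
          lower = c(-Inf, -Inf, 1e-12, -Inf, 1e-12),
          max_iterations = max_iterations, tolerance = tolerance)
}

run_fit <- function(window, start, model, init, lower,
                    max_iterations, tolerance) {
  predict_fn <- if (model == "single") predict_single else predict_double
  resid_fn <- function(par) {
    names(par) <- names(start)
    window$y - predict_fn(par, window$t_rel)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = max_iterations,
                         ptol = tolerance, ftol = tolerance)),
    error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(unlist(fit$par)))) {
    par <- start
    converged <- FALSE
  } else {
    par <- unlist(fit$par)
    names(par) <- names(start)
    # info 1-3: ftol/ptol convergence; 4: gradient orthogonality (gtol);
    # 0 improper input, 5+ iteration/evaluation caps hit
    converged <- fit$info %in% 1:4
  }
  if (model == "double" && par[["k1"]] < par[["k2"]]) {
    par <- par[c("y0", "a2", "k2", "a1", "k1")]
    names(par) <- c("y0", "a1", "k1", "a2", "k2")
  }
  gof <- goodness_of_fit(window$y, predict_fn(par, window$t_rel),
                         p = length(par))
  new_ca_fit(model = model, par = par, gof = gof,
             n_points = nrow(window), init = init, converged = converged,
             window = window)
}

# Low-level constructor; also used by tests building fits from known stats.
new_ca_fit <- function(model, par, gof, n_points, init = NULL,
                       converged = TRUE, window = NULL) {
  zeroed <- if (is.null(window)) FALSE else isTRUE(attr(window, "zeroed"))
  offset <- if (is.null(window)) 0 else window_offset(window)
  par[["y0"]] <- par[["y0"]] + offset  # report baseline in original units
  structure(list(
    model = model,
    coefficients = par,
    ss_reg = gof$ss_reg,
    ss_total = gof$ss_total,
    r_squared = gof$r_squared,
    adjusted_r_squared = gof$adjusted_r_squared,
    gof_undefined = isTRUE(gof$undefined),
    n_points = n_points,
    n_params = length(par),
    initial_guess = init,
    converged = converged,
    zeroed = zeroed,
    offset = offset,
    region = if (is.null(window)) NULL else attr(window, "region"),
    label = if (is.null(window)) "" else attr(window, "label") %||% "",
    window = window
  ), class = "ca_fit")
}

#' @export
print.ca_fit <- function(x, ...) {
  cat(sprintf("<ca_fit> %s exponential, %d points%s%s\n",
              x$model, x$n_points,
              if (x$converged) "" else " [NOT CONVERGED]",
              if (x$gof_undefined) " [R² undefined: zero variance]" else ""))
  print(signif(x$coefficients, 6))
  if (!x$gof_undefined) {
    cat(sprintf("  SSreg = %.6g  R² = %.4f  adj R² = %.4f\n",
                x$ss_reg, x$r_squared, x$adjusted_r_squared))
  }
  invisible(x)
}

#' @export
coef.ca_fit <- function(object, ...) object$coefficients

#' Predicted decay curve of a fit
#'
#' @param object A `ca_fit`.
#' @param t_rel Times (ms from window start) at which to evaluate; defaults
#'   to the fitted window's times.
#' @param ... Unused.
#' @return Numeric vector of predicted values in original signal units.
#' @export
predict.ca_fit <- function(object, t_rel = NULL, ...) {
  if (is.null(t_rel)) t_rel <- object$window$t_rel
  par <- object$coefficients
  par[["y0"]] <- par[["y0"]] - object$offset  # back to the fitted frame
  pred <- if (object$model == "single") predict_single(par, t_rel)
          else predict_double(par, t_rel)
  pred + object$offset
}

#' Fit single and double exponentials simultaneously
#'
#' Runs both regressions on the identical window, so their goodness-of-fit
#' statistics are directly comparable; pass the pair to
#' [indicate_best_fit()] to select the more reliable description.
#'
#' @param window A fit window from [extract_fit_window()].
#' @param y0_cursor,peak_cursor Cursor levels for the initial guesses.
#' @param divisors Length-4 positive numeric `(a, b, c, d)` splitting the
#'   single-model guess into double-model starting values; see
#'   [initial_guess_double()].
#' @param smart_rc Use tau-based rate prediction for the initial k?
#' @inheritParams fit_single
#' @return A list with elements `single` and `double`, each a `ca_fit`.
#' @export
fit_simultaneous <- function(window, y0_cursor, peak_cursor,
                             divisors = c(2, 2, 0.5, 2), smart_rc = TRUE,
                             max_iterations = 1000, tolerance = 1e-10) {
  window <- as_fit_window(window)
  gs <- initial_guess_single(window, y0_cursor, peak_cursor, smart_rc = smart_rc)
  gd <- initial_guess_double(gs, divisors[1L], divisors[2L],
                             divisors[3L], divisors[4L])
  list(single = fit_single(window, gs, max_iterations, tolerance),
       double = fit_double(window, gd, max_iterations, tolerance))
}

#' Indicate which of two simultaneous fits is more reliable
#'
#' Compares the adjusted R-squared of a single- and a double-exponential fit
#' performed on the same window; the parameter-count penalty makes the
#' nested models directly comparable. Ties (difference below 1e-12) go to
#' the single model by parsimony.
#'
#' @param single,double `ca_fit` objects from the same window.
#' @return `"single"` or `"double"`.
#' @examples
#' w <- tibble::tibble(t_rel = 0:199, y = 1 + 0.5 * exp(-0.01 * (0:199)))
#' fits <- fit_simultaneous(w, 1, 1.5)
#' indicate_best_fit(fits$single, fits$double)
#' @export
indicate_best_fit <- function(single, double) {
  if (!inherits(single, "ca_fit") || !inherits(double, "ca_fit")) {
    stop("indicate_best_fit takes two ca_fit objects", call. = FALSE)
  }
  if (single$model != "single" || double$model != "double") {
    stop("pass the single fit first and the double fit second", call. = FALSE)
  }
  if (single$n_points != double$n_points) {
    stop("fits are not comparable: windows differ (", single$n_points,
         " vs ", double$n_points, " points)", call. = FALSE)
  }
  if (is.na(single$adjusted_r_squared) || is.na(double$adjusted_r_squared)) {
    stop("adjusted R² undefined for at least one fit", call. = FALSE)
  }
  delta <- double$adjusted_r_squared - single$adjusted_r_squared
  if (delta > 1e-12) "double" else "single"
}

#' Fit the decay of a transient in one call
#'
#' High-level wrapper over the regression stage: extracts the fit window,
#' builds the cursor-derived initial guesses, runs the requested
#' regression(s), and (for `model = "both"`) indicates the best fit.
#'
#' @param trace A prepared [ca_trace()].
#' @param reg [region()] flanking the decay phase.
#' @param y0_cursor,peak_cursor Baseline and peak cursor levels in signal
#'   units (pre-zeroing units; the zero offset is handled internally).
#' @param model `"single"`, `"double"`, or `"both"`.
#' @param zero_fit_range Subtract the baseline cursor from the window before
#'   fitting (optimizer conditioning; results are re-offset on output).
#' @param smart_rc Use tau-based initial-rate prediction.
#' @param divisors Double-model guess divisors `(a, b, c, d)`.
#' @inheritParams fit_single
#' @return For `"single"`/`"double"`, a `ca_fit`. For `"both"`, a list with
#'   `single`, `double`, and `best` (the [indicate_best_fit()] verdict).
#' @examples
#' tr <- make_transient(transient_spec(seed = 7))
#' fit_decay(tr, region(60, 1400), y0_cursor = 1, peak_cursor = 1.5)
#' @export
fit_decay <- function(trace, reg, y0_cursor, peak_cursor,
                      model = c("single", "double", "both"),
                      zero_fit_range = FALSE, smart_rc = TRUE,
                      divisors = c(2, 2, 0.5, 2),
                      max_iterations = 1000, tolerance = 1e-10) {
  model <- match.arg(model)
  window <- extract_fit_window(trace, reg, zero = zero_fit_range,
                               y0_cursor = y0_cursor)
  # cursors refer to the original units; express them in the window's frame
  off <- window_offset(window)
  y0_w <- y0_cursor - off
  peak_w <- peak_cursor - off
  if (model == "both") {
    fits <- fit_simultaneous(window, y0_w, peak_w, divisors = divisors,
                             smart_rc = smart_rc,
                             max_iterations = max_iterations,
                             tolerance = tolerance)
    fits$best <- indicate_best_fit(fits$single, fits$double)
    return(fits)
  }
  gs <- initial_guess_single(window, y0_w, peak_w, smart_rc = smart_rc)
  if (model == "single") {
    fit_single(window, gs, max_iterations, tolerance)
  } else {
    gd <- initial_guess_double(gs, divisors[1L], divisors[2L],
                               divisors[3L], divisors[4L])
    fit_double(window, gd, max_iterations, tolerance)
  }
}
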