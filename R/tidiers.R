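#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a decay fit into one row per parameter
#'
#' @param x A `ca_fit` from [fit_single()], [fit_double()] or [fit_decay()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `initial` (the starting
#'   value the optimizer was given, in the same reported units).
#' @exportS3Method generics::tidy
#' @export
tidy.ca_fit <- function(x, ...) {
  terms <- names(x$coefficients)
  init <- x$initial_guess
  initial <- rep(NA_real_, length(terms))
  if (!is.null(init)) {
    pick <- if (x$model == "single") {
      c(y0 = init$y0, a = init$a, k = init$k)
    } else {
      c(y0 = init$y0, a1 = init$a1, k1 = init$k1, a2 = init$a2, k2 = init$k2)
    }
    initial <- unname(pick[terms])
    initial[terms == "y0"] <- initial[terms == "y0"] + x$offset
  }
  tibble::tibble(term = terms,
                 estimate = unname(x$coefficients),
                 initial = initial)
}

#' One-row goodness-of-fit summary of a decay fit
#'
#' @param x A `ca_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `ss_reg`, `ss_total`, `r.squared`,
#'   `adj.r.squared`, `nobs`, `n_params`, `converged`, `zeroed`.
#' @export
glance.ca_fit <- function(x, ...) {
  tibble::tibble(model = x$model,
                 ss_reg = x$ss_reg,
                 ss_total = x$ss_total,
                 r.squared = x$r_squared,
                 adj.r.squared = x$adjusted_r_squared,
                 nobs = x$n_points,
                 n_params = x$n_params,
                 converged = x$converged,
                 zeroed = x$zeroed)
}

#' Plot a trace
#'
#' @param object A [ca_trace()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.ca_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::labs(x = "time (ms)", y = signal_axis_label(signal_kind(object)),
                  title = trace_label(object)) +
    ggplot2::theme_minimal()
}

signal_axis_label <- function(kind) {
  switch(kind,
         raw = "fluorescence (a.u.)",
         background_subtracted = "F (a.u.)",
         ratio = "ratio",
         f_over_f0 = expression(F / F[0]),
         calcium_nM = "[Ca] (nM)",
         "signal")
}

#' Plot a decay fit over its data
#'
#' Overlays the fitted exponential on the fit-window data (in original
#' signal units). When the initial rate constant was predicted from the
#' curve's time constant, the position of tau is marked with a vertical
#' line.
#'
#' @param object A `ca_fit`.
#' @param show_tau Mark the tau estimate used for the initial guess?
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.ca_fit <- function(object, show_tau = TRUE, ...) {
  if (is.null(object$window)) {
    stop("this fit carries no data window to plot", call. = FALSE)
  }
  dat <- tibble::tibble(t_rel = object$window$t_rel,
                        y = object$window$y + object$offset,
                        fit = predict(object))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$t_rel)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$y), colour = "grey55") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), colour = "black",
                       linetype = "dashed", linewidth = 0.8) +
    ggplot2::labs(x = "time from window start (ms)", y = "signal",
                  title = sprintf("%s exponential fit%s", object$model,
                                  if (nzchar(object$label)) paste0(": ", object$label) else "")) +
    ggplot2::theme_minimal()
  init <- object$initial_guess
  if (isTRUE(show_tau) && !is.null(init) && isTRUE(init$smart_rc)) {
    p <- p + ggplot2::geom_vline(xintercept = init$tau, colour = "steelblue",
                                 linetype = "dotted")
  }
  p
}

#' Plot a simultaneous single/double fit comparison
#'
#' @param fits A list with `ca_fit` elements `single` and `double`, e.g.
#'   from [fit_simultaneous()] or `fit_decay(model = "both")`.
#' @return A ggplot overlaying the data and both fitted curves.
#' @export
plot_fit_comparison <- function(fits) {
  s <- fits$single; d <- fits$double
  dat <- tibble::tibble(t_rel = s$window$t_rel,
                        y = s$window$y + s$offset,
                        single = predict(s),
                        double = predict(d))
  long <- tidyr::pivot_longer(dat, c("single", "double"),
                              names_to = "model", values_to = "fit")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_rel)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$y), colour = "grey55") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit, colour = .data$model),
                       linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = c(single = "firebrick",
                                            double = "steelblue")) +
    ggplot2::labs(x = "time from window start (ms)", y = "signal") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
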