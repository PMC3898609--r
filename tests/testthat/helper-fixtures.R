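# Shared fixture builders. All synthetic data is generated in code with
# fixed seeds; nothing is read from disk except files the tests write.

# Generating parameters at the magnitudes of published myocyte fits:
# an F/F0-scale single-exponential decay and a calibrated-scale (nM)
# double-exponential decay.
mono_truth <- function() list(y0 = 2.217389, a = 0.688976, k = 0.003334)
bi_truth <- function() list(y0 = 57.96, a1 = 64.19, k1 = 0.017,
                            a2 = 59.76, k2 = 0.0012)

# A bare fit window holding an exact mono-exponential decay (no upstroke).
mono_window <- function(truth = mono_truth(), n = 1000, dt = 1,
                        noise_sd = 0, seed = NULL) {
  t <- seq(0, by = dt, length.out = n)
  y <- truth$y0 + truth$a * exp(-truth$k * t)
  if (noise_sd > 0) {
    stopifnot(!is.null(seed))
    y <- y + catransient:::local_rnorm(seed, n, sd = noise_sd)
  }
  tibble::tibble(t_rel = t, y = y)
}

bi_window <- function(truth = bi_truth(), n = 3000, dt = 1,
                      noise_sd = 0, seed = NULL) {
  t <- seq(0, by = dt, length.out = n)
  y <- truth$y0 + truth$a1 * exp(-truth$k1 * t) + truth$a2 * exp(-truth$k2 * t)
  if (noise_sd > 0) {
    stopifnot(!is.null(seed))
    y <- y + catransient:::local_rnorm(seed, n, sd = noise_sd)
  }
  tibble::tibble(t_rel = t, y = y)
}

# Cursor levels read off a window the way a user would place the Y-cursors.
window_cursors <- function(w) list(y0 = min(w$y), peak = max(w$y))

# Independent brute-force oracle: minimum residual sum of squares of the
# single-exponential model over an exhaustive 3-D grid spanning
# +/- span around the given centre, points^3 evaluations.
grid_oracle_ss <- function(w, centre, span = 0.5, points = 21L) {
  grid_axis <- function(v) seq(v * (1 - span), v * (1 + span), length.out = points)
  best <- Inf
  for (y0 in grid_axis(centre$y0)) {
    for (a in grid_axis(centre$a)) {
      for (k in grid_axis(centre$k)) {
        ss <- sum((w$y - (y0 + a * exp(-k * w$t_rel)))^2)
        if (ss < best) best <- ss
      }
    }
  }
  best
}

# A fit record built from known goodness-of-fit numbers (no optimizer run);
# used to test the model-comparison rule in isolation.
fit_stub <- function(model, ss_reg, ss_total, n_points) {
  p <- if (model == "single") 3L else 5L
  par <- if (model == "single") {
    c(y0 = 0, a = 1, k = 0.01)
  } else {
    c(y0 = 0, a1 = 1, k1 = 0.02, a2 = 1, k2 = 0.001)
  }
  gof <- list(ss_reg = ss_reg, ss_total = ss_total,
              r_squared = 1 - ss_reg / ss_total,
              adjusted_r_squared =
                1 - (ss_reg / (n_points - p)) / (ss_total / (n_points - 1)),
              undefined = FALSE)
  catransient:::new_ca_fit(model = model, par = par, gof = gof,
                           n_points = n_points)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
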