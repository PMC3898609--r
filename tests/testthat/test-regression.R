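test_that("fit windows re-zero time and optionally offset the values", {
  tr <- ca_trace(95:110, seq(3, by = -0.1, length.out = 16))
  w <- extract_fit_window(tr, region(100, 106))
  expect_equal(w$t_rel, 0:6)
  expect_equal(w$y[1], 2.5)

  wz <- extract_fit_window(tr, region(100, 106), zero = TRUE, y0_cursor = 2)
  expect_equal(wz$y, w$y - 2)
  expect_true(attr(wz, "zeroed"))
  expect_equal(catransient:::window_offset(wz), 2)

  expect_error(extract_fit_window(tr, region(100, 104)), "at least 6")
})

test_that("tau is read off the curve at the 1/e level between the cursors", {
  # pure decay, tau = 100 ms: crossing detected within one sample interval
  w <- tibble::tibble(t_rel = 0:500, y = 1 + 0.5 * exp(-(0:500) / 100))
  tau <- estimate_tau(w, 1, 1.5)
  expect_lte(abs(as.numeric(tau) - 100), 1)
  expect_false(attr(tau, "fallback"))

  # linear decay dropping below the 1/e level at t = 40
  level <- 1 + 0.5 / exp(1)
  yl <- 1.5 - (1.5 - level) * (0:100) / 39.5
  tau_l <- estimate_tau(tibble::tibble(t_rel = 0:100, y = yl), 1, 1.5)
  expect_equal(as.numeric(tau_l), 40)

  # never crossing: half the window duration, flagged
  wf <- tibble::tibble(t_rel = 0:200, y = rep(1.4, 201))
  tau_f <- estimate_tau(wf, 1, 1.5)
  expect_equal(as.numeric(tau_f), 100)
  expect_true(attr(tau_f, "fallback"))

  expect_error(estimate_tau(w, 1.5, 1), "above the baseline")

  # seeded noisy monoexponential, k = 0.005/ms: 1/tau within 25% of truth
  truth <- list(y0 = 1, a = 0.5, k = 0.005)
  wn <- mono_window(truth, n = 1000, noise_sd = 0.01, seed = 29)
  tau_n <- as.numeric(estimate_tau(wn, 1, 1.5))
  expect_lt(abs(1 / tau_n - 0.005) / 0.005, 0.25)
})

test_that("single-model first guess composes the cursors with the tau prediction", {
  w <- tibble::tibble(t_rel = 0:500, y = 1 + 0.5 * exp(-(0:500) / 100))
  g <- initial_guess_single(w, 1.0, 1.5)
  expect_equal(g$y0, 1.0)
  expect_equal(g$a, 0.5)
  expect_equal(g$k, 1 / g$tau)
  expect_lt(abs(g$k - 0.01) / 0.01, 0.02)
  expect_error(initial_guess_single(w, 1.2, 1.2), "above the baseline")

  # smart prediction off: k falls back to 1/(window duration / 5)
  g_off <- initial_guess_single(w, 1.0, 1.5, smart_rc = FALSE)
  expect_equal(g_off$k, 5 / 500)
})

test_that("the tau-based guess lands within a factor 2 of the true k on noisy data", {
  truth <- list(y0 = 1, a = 0.5, k = 0.0033)
  hits <- 0L
  for (i in 1:100) {
    w <- mono_window(truth, n = 1200, noise_sd = 0.02, seed = 1000L + i)
    cur <- window_cursors(w)
    g <- initial_guess_single(w, cur$y0, cur$peak)
    if (g$k > truth$k / 2 && g$k < truth$k * 2) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("double-model first guess divides amplitude and rate by the user constants", {
  w <- tibble::tibble(t_rel = 0:500, y = 1 + 0.6 * exp(-(0:500) / 100))
  g <- initial_guess_single(w, 1.0, 1.6)
  g$a <- 0.6; g$k <- 0.01  # pin exact values for the arithmetic check
  gd <- initial_guess_double(g, 2, 2, 0.5, 2)
  expect_equal(gd$a1, 0.3)
  expect_equal(gd$a2, 0.3)
  expect_equal(gd$k1, 0.02)
  expect_equal(gd$k2, 0.005)

  # identity divisors leave the single-model guess untouched
  gi <- initial_guess_double(g, 1, 1, 1, 1)
  expect_equal(c(gi$a1, gi$a2, gi$k1, gi$k2), c(0.6, 0.6, 0.01, 0.01))

  expect_error(initial_guess_double(g, 0, 2, 0.5, 2), "positive")
  expect_error(initial_guess_double(g, 2, 2, -1, 2), "positive")
})

test_that("noiseless single-exponential fits recover the generating parameters", {
  truth <- mono_truth()
  w <- mono_window(truth, n = 1000)
  cur <- window_cursors(w)
  fit <- fit_single(w, initial_guess_single(w, cur$y0, cur$peak))
  expect_true(fit$converged)
  cf <- coef(fit)
  expect_rel_equal(cf[["y0"]], truth$y0, 1e-6)
  expect_rel_equal(cf[["a"]], truth$a, 1e-6)
  expect_rel_equal(cf[["k"]], truth$k, 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_identical(fit$n_params, 3L)
})

test_that("a constant window yields a flagged zero-variance result, not a crash", {
  w <- tibble::tibble(t_rel = 0:20, y = rep(2, 21))
  g <- initial_guess_single(w, 1.9, 2.1)
  fit <- fit_single(w, g)
  expect_true(fit$gof_undefined)
  expect_true(is.na(fit$r_squared))
  expect_equal(fit$ss_total, 0)
  # the flat data are fit exactly (the amplitude term contributes a constant)
  expect_lt(fit$ss_reg, 1e-12)
})

test_that("optimizer failure returns a non-converged result echoing the guess", {
  w <- tibble::tibble(t_rel = 0:10, y = c(rep(1, 10), 2))
  g <- initial_guess_single(w, 0.5, 3)
  g$k <- NaN  # poisoned guess: nls.lm cannot start
  fit <- fit_single(w, g)
  expect_false(fit$converged)
  expect_identical(fit$initial_guess, g)
})

test_that("the optimum beats an exhaustive parameter grid around the truth", {
  truth <- list(y0 = 1, a = 0.5, k = 0.01)
  w <- mono_window(truth, n = 50, dt = 10, noise_sd = 0.01, seed = 37)
  cur <- window_cursors(w)
  fit <- fit_single(w, initial_guess_single(w, cur$y0, cur$peak))
  oracle <- grid_oracle_ss(w, truth, span = 0.5, points = 21L)
  expect_true(fit$converged)
  expect_lte(fit$ss_reg, oracle)
})

test_that("noiseless double-exponential fits recover the generating parameters", {
  truth <- bi_truth()
  w <- bi_window(truth, n = 3000)
  cur <- window_cursors(w)
  gd <- initial_guess_double(initial_guess_single(w, cur$y0, cur$peak))
  fit <- fit_double(w, gd)
  expect_true(fit$converged)
  cf <- coef(fit)
  expect_rel_equal(cf[["y0"]], truth$y0, 1e-4)
  expect_rel_equal(cf[["a1"]], truth$a1, 1e-4)
  expect_rel_equal(cf[["k1"]], truth$k1, 1e-4)
  expect_rel_equal(cf[["a2"]], truth$a2, 1e-4)
  expect_rel_equal(cf[["k2"]], truth$k2, 1e-4)
  expect_identical(fit$n_params, 5L)
})

test_that("the double fit collapses gracefully on mono-generated data", {
  truth <- list(y0 = 1, a1 = 0.5, k1 = 0.0033, a2 = 0, k2 = 0.0001)
  w <- bi_window(truth, n = 1500)
  cur <- window_cursors(w)
  gd <- initial_guess_double(initial_guess_single(w, cur$y0, cur$peak))
  fit <- fit_double(w, gd)
  cf <- coef(fit)
  # either one amplitude vanishes or the two rates coincide
  collapse <- min(abs(cf[["a1"]]), abs(cf[["a2"]])) < 1e-6 * max(abs(cf[["a1"]]), abs(cf[["a2"]])) ||
    abs(cf[["k1"]] - cf[["k2"]]) / cf[["k1"]] < 1e-3
  expect_true(collapse)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("fitted double components are reported fast-first regardless of generator order", {
  base <- bi_truth()
  swapped <- list(y0 = base$y0, a1 = base$a2, k1 = base$k2,
                  a2 = base$a1, k2 = base$k1)
  w1 <- bi_window(base, n = 2000)
  w2 <- bi_window(swapped, n = 2000)
  expect_equal(w1$y, w2$y, tolerance = 1e-12)  # symmetry of the model
  cur <- window_cursors(w1)
  gd <- initial_guess_double(initial_guess_single(w1, cur$y0, cur$peak))
  f1 <- fit_double(w1, gd)
  f2 <- fit_double(w2, gd)
  expect_gte(coef(f1)[["k1"]], coef(f1)[["k2"]])
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
})

test_that("goodness of fit follows the residual and total sums of squares", {
  y <- c(1, 2, 3, 4, 5, 6)
  expect_equal(goodness_of_fit(y, y, p = 3)$r_squared, 1)
  expect_equal(goodness_of_fit(y, y, p = 3)$adjusted_r_squared, 1)
  null_fit <- goodness_of_fit(y, rep(mean(y), 6), p = 1)
  expect_equal(null_fit$r_squared, 0)
  expect_equal(null_fit$ss_reg, null_fit$ss_total)

  const <- goodness_of_fit(rep(2, 6), rep(2, 6), p = 3)
  expect_true(const$undefined)
  expect_error(goodness_of_fit(y, y[1:3], p = 1), "lengths differ")
  expect_error(goodness_of_fit(y[1:3], y[1:3], p = 3), "n > p")

  # at n ~ 1e3 the adjustment is negligible relative to the unexplained part
  truth <- list(y0 = 1, a = 0.5, k = 0.0033)
  w <- mono_window(truth, n = 1000, noise_sd = 0.02, seed = 43)
  pred <- truth$y0 + truth$a * exp(-truth$k * w$t_rel)
  g <- goodness_of_fit(w$y, pred, p = 3)
  expect_lt(abs(g$adjusted_r_squared - g$r_squared), 0.01 * (1 - g$r_squared) * 10)
})

test_that("adjusted R-squared stays at or below R-squared for n > p", {
  set.seed(53)
  for (i in 1:20) {
    n <- sample(10:500, 1)
    y <- stats::rnorm(n)
    pred <- y + stats::rnorm(n, sd = 0.3)
    g <- goodness_of_fit(y, pred, p = sample(3:5, 1))
    expect_lte(g$adjusted_r_squared, g$r_squared + 1e-12)
    expect_gte(g$ss_reg, 0)
  }
})

test_that("shift, time-origin and zeroing invariances hold for the fitted rate", {
  truth <- list(y0 = 1, a = 0.5, k = 0.0033)
  w <- mono_window(truth, n = 1000, noise_sd = 0.01, seed = 59)
  cur <- window_cursors(w)
  fit <- fit_single(w, initial_guess_single(w, cur$y0, cur$peak))

  # adding a constant moves Y0 only
  w_shift <- dplyr::mutate(w, y = y + 7)
  fs <- fit_single(w_shift, initial_guess_single(w_shift, cur$y0 + 7, cur$peak + 7))
  expect_lt(abs(coef(fs)[["y0"]] - coef(fit)[["y0"]] - 7), 1e-8)
  expect_lt(abs(coef(fs)[["a"]] - coef(fit)[["a"]]), 1e-8)
  expect_lt(abs(coef(fs)[["k"]] - coef(fit)[["k"]]), 1e-8)

  # the absolute start time of the window never enters the model
  spec <- transient_spec(noise_sd = 0.01, seed = 61)
  tr <- make_transient(spec)
  shifted <- ca_trace(tr$time + 5000, tr$value)
  dw <- decay_window_spec(spec)
  f1 <- fit_decay(tr, dw$region, dw$y0_cursor, dw$peak_cursor, model = "single")
  f2 <- fit_decay(shifted, region(dw$region$t_start + 5000, dw$region$t_end + 5000),
                  dw$y0_cursor, dw$peak_cursor, model = "single")
  expect_equal(coef(f1)[["k"]], coef(f2)[["k"]], tolerance = 1e-10)

  # zero-fit-range is an optimizer conditioning aid only
  fz <- fit_decay(tr, dw$region, dw$y0_cursor, dw$peak_cursor,
                  model = "single", zero_fit_range = TRUE)
  expect_rel_equal(coef(fz)[["k"]], coef(f1)[["k"]], 1e-6)
  expect_equal(coef(fz)[["y0"]], coef(f1)[["y0"]], tolerance = 1e-5)
  expect_true(fz$zeroed)
})

test_that("simultaneous fits share the window and feed model indication", {
  # mono-generated data: the two nested models explain it equally well
  truth <- list(y0 = 1, a = 0.5, k = 0.0033)
  w <- mono_window(truth, n = 1000, noise_sd = 0.01, seed = 67)
  cur <- window_cursors(w)
  fits <- fit_simultaneous(w, cur$y0, cur$peak)
  expect_identical(fits$single$n_points, fits$double$n_points)
  expect_lt(abs(fits$single$adjusted_r_squared - fits$double$adjusted_r_squared),
            1e-3)

  # strongly biexponential data: the double fit wins on adjusted R-squared
  truthb <- list(y0 = 58, a1 = 64, k1 = 0.017, a2 = 60, k2 = 0.0012)  # k1/k2 ~ 14
  wb <- bi_window(truthb, n = 2500, noise_sd = 2, seed = 71)
  curb <- window_cursors(wb)
  fb <- fit_simultaneous(wb, curb$y0, curb$peak)
  expect_gt(fb$double$adjusted_r_squared, fb$single$adjusted_r_squared)
  expect_identical(indicate_best_fit(fb$single, fb$double), "double")
})

test_that("best-fit indication uses adjusted R-squared with a parsimony tie-break", {
  # goodness-of-fit pair at the published simultaneous-fit magnitudes:
  # SSreg 79588 vs 6562.1 on the same window, R-squared 0.9448 vs 0.9954
  ss_total <- 79588 / (1 - 0.9448)
  single <- fit_stub("single", 79588, ss_total, n_points = 1500)
  double <- fit_stub("double", 6562.1, ss_total, n_points = 1500)
  expect_equal(single$r_squared, 0.9448, tolerance = 1e-4)
  expect_equal(double$r_squared, 0.9954, tolerance = 1e-4)
  expect_identical(indicate_best_fit(single, double), "double")

  # exact tie goes to the simpler model
  s2 <- fit_stub("single", 1000, 10000, n_points = 1000)
  d2 <- fit_stub("double", 1000 * (1000 - 5) / (1000 - 3), 10000, n_points = 1000)
  expect_equal(s2$adjusted_r_squared, d2$adjusted_r_squared, tolerance = 1e-13)
  expect_identical(indicate_best_fit(s2, d2), "single")

  d3 <- fit_stub("double", 900, 10000, n_points = 500)
  expect_error(indicate_best_fit(s2, d3), "windows differ")
  expect_error(indicate_best_fit(d3, d3), "single fit first")
})

test_that("mono-generated data selects the single model in a clear majority of runs", {
  # On mono truth the double fit can always capture some noise; the
  # parameter-count penalty of adjusted R-squared rejects it only when the
  # captured gain falls below ~2 noise variances, so the rule is a lenient
  # nested-model test (ideal-optimizer specificity ~63%, in practice higher
  # because the optimizer rarely extracts the full degenerate-direction
  # gain). Assert a clear majority, well above both chance and that floor.
  truth <- list(y0 = 1, a = 0.5, k = 0.0033)
  wins <- 0L
  for (i in 1:50) {
    w <- mono_window(truth, n = 800, noise_sd = 0.01, seed = 2000L + i)
    cur <- window_cursors(w)
    fits <- fit_simultaneous(w, cur$y0, cur$peak)
    if (indicate_best_fit(fits$single, fits$double) == "single") wins <- wins + 1L
  }
  expect_gte(wins, 35L)
})

test_that("double-model guesses at the defaults recover a well-separated biexponential", {
  truth <- list(y0 = 1, a1 = 0.3, k1 = 0.02, a2 = 0.3, k2 = 0.002)  # k1/k2 = 10
  w <- bi_window(truth, n = 2500, noise_sd = 0.003, seed = 73)
  cur <- window_cursors(w)
  gd <- initial_guess_double(initial_guess_single(w, cur$y0, cur$peak))
  fit <- fit_double(w, gd)
  expect_true(fit$converged)
  expect_rel_equal(coef(fit)[["k1"]], truth$k1, 0.05)
  expect_rel_equal(coef(fit)[["k2"]], truth$k2, 0.05)
})
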