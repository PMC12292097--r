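test_that("nrmse matches hand-computed values and its invariances", {
  x <- c(3, 4)
  expect_equal(nrmse(x, x), 0)
  expect_equal(nrmse(x, c(0, 0)), 1)
  expect_equal(nrmse(x, c(3, 0)), 4 / 5)
  set.seed(1)
  a <- stats::rnorm(50); b <- stats::rnorm(50)
  expect_equal(nrmse(a, b), nrmse(3.7 * a, 3.7 * b))
  expect_error(nrmse(c(0, 0), c(1, 2)), "identically zero")
  expect_error(nrmse(1:3, 1:4), "equal length")
})

test_that("trace normalization preserves sign and sets unit peak", {
  expect_equal(max(normalize_trace(c(0, 0.02, 0.04, 0.01))), 1)
  y <- c(-0.2, -1.5, -0.7)
  expect_equal(min(normalize_trace(y)), -1)
  z <- c(0, 0.5, 1, 0.2)
  expect_equal(normalize_trace(z), z)
  expect_error(normalize_trace(c(0, 0)), "all-zero")
})

test_that("detect_peaks equals a windowed maximum on simulated trains", {
  sch <- build_scheme("optimized")
  sim <- simulate_scheme(sch, square_pulse_train(10, 3, 1, 1000), 300,
                         dt = 0.01)
  pulse_times <- c(0, 100, 200)
  got <- detect_peaks(sim$time, sim$open_probability, pulse_times)
  bounds <- c(pulse_times, Inf)
  oracle <- vapply(1:3, function(k)
    max(sim$open_probability[sim$time >= bounds[k] & sim$time < bounds[k + 1]]),
    numeric(1))
  expect_equal(got, oracle)
  expect_true(all(got > 0))
  expect_equal(detect_peaks(sim$time, rep(0, length(sim$time)), pulse_times),
               c(0, 0, 0))
  expect_error(detect_peaks(sim$time, sim$open_probability, c(0, 400)),
               "cover")
})

test_that("fdhm matches closed-form widths", {
  # symmetric triangle, base 10 ms peaking at 5 ms -> width at half max 5 ms
  tt <- seq(0, 10, by = 0.001)
  tri <- pmax(0, 1 - abs(tt - 5) / 5)
  expect_equal(fdhm(tt, tri), 5, tolerance = 1e-3)
  # instantaneous rise, monoexponential decay: fdhm = tau log 2
  tt2 <- seq(0, 1000, by = 0.01)
  expect_equal(fdhm(tt2, exp(-tt2 / 100)), 100 * log(2), tolerance = 1e-2)
  expect_error(fdhm(tt2, tt2 / 1000), "falls back")
  expect_error(fdhm(tt2, -exp(-tt2 / 100)), "positive peak")
})

test_that("fdhm of the basis waveform matches a dense-grid crossing search", {
  bp <- basis_params(5, 60, 250)
  tt <- seq(0, 3000, by = 0.5)
  w <- basis_waveform(tt, bp)
  got <- fdhm(tt, w)
  fine <- seq(0, 3000, by = 0.001)
  wf <- basis_waveform(fine, bp)
  above <- which(wf >= max(wf) / 2)
  oracle <- fine[max(above)] - fine[min(above)]
  expect_equal(got, oracle, tolerance = 0.1)
})

test_that("biexponential fitting recovers known decay parameters", {
  tt <- seq(0, 1500, by = 0.5)
  # degenerate: pure monoexponential
  fit <- fit_biexponential(tt, exp(-tt / 100))
  expect_equal(fit$weighted_tau, 100, tolerance = 1e-2)
  # equal amplitudes: weighted tau is the midpoint
  y <- 0.5 * exp(-tt / 50) + 0.5 * exp(-tt / 150)
  fit2 <- fit_biexponential(tt, y)
  expect_equal(fit2$weighted_tau, 100, tolerance = 0.02)
  expect_lte(fit2$tau1, fit2$tau2)
  expect_equal((fit2$A1 * fit2$tau1 + fit2$A2 * fit2$tau2) /
                 (fit2$A1 + fit2$A2), fit2$weighted_tau)
  # grid of noiseless biexponentials: taus recovered within 5%
  cases <- expand.grid(tau1 = c(20, 50, 80), tau2 = c(200, 400),
                       a1 = c(0.3, 0.6))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    y <- cs$a1 * exp(-tt / cs$tau1) + (1 - cs$a1) * exp(-tt / cs$tau2)
    f <- fit_biexponential(tt, y, normalize = FALSE)
    expect_lt(abs(f$tau1 - cs$tau1) / cs$tau1, 0.05)
    expect_lt(abs(f$tau2 - cs$tau2) / cs$tau2, 0.05)
  }
})
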