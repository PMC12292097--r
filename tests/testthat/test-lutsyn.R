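test_that("Fnorm matches the closed-form double-exponential case", {
  # Tc2 = Tc3 collapses the basis to Fnorm * (e^(-t/150) - e^(-t/5));
  # argmax t* = ln(30) * (5*150/145), max value computable in closed form
  fn <- compute_fnorm(5, 150, 150, w = 0.3)
  tstar <- log(30) * (5 * 150 / 145)
  fmax <- exp(-tstar / 150) - exp(-tstar / 5)
  expect_equal(fn$Fnorm, 1 / fmax, tolerance = 1e-6)
  expect_equal(fn$t_peak, tstar, tolerance = 1e-4)
  # time rescaling leaves Fnorm unchanged
  fn2 <- compute_fnorm(10, 300, 300, w = 0.3)
  expect_equal(fn2$Fnorm, fn$Fnorm, tolerance = 1e-6)
  expect_error(compute_fnorm(150, 5, 5), "non-positive maximum")
})

test_that("basis waveforms start at zero, peak at one, and vanish", {
  for (tc in list(c(3, 40, 150), c(5, 60, 250), c(10, 100, 800))) {
    bp <- basis_params(tc[1], tc[2], tc[3])
    expect_equal(basis_waveform(0, bp), 0)
    tt <- seq(0, 12 * tc[3], by = 0.05)
    w <- basis_waveform(tt, bp)
    expect_equal(max(w), 1, tolerance = 1e-4)
    expect_true(all(w >= 0 & w <= 1 + 1e-9))
    expect_lt(w[length(w)], 1e-3)
    expect_equal(basis_waveform(-5, bp), 0)
  }
  # Tc2 = Tc3 reduces to a double exponential regardless of w
  bp <- basis_params(5, 120, 120, w = 0.7384)
  tt <- seq(0, 500, by = 0.1)
  expect_equal(basis_waveform(tt, bp),
               bp$Fnorm * (exp(-tt / 120) - exp(-tt / 5)))
})

test_that("order categorization follows the sliding memory window", {
  expect_equal(categorize_orders(0), 1L)
  expect_equal(categorize_orders(c(0, 500, 1600), M = 1000), c(1L, 2L, 1L))
  expect_equal(categorize_orders(seq(0, 500, by = 100), M = 1000),
               c(1L, 2L, 3L, 4L, 5L, 5L))
  expect_equal(categorize_orders(c(0, 999, 1000, 2500), M = 1000),
               c(1L, 2L, 3L, 1L))
  expect_error(categorize_orders(c(5, 1)), "sorted")
})

test_that("interval quantization rounds to the nearest step, ties up, min delta", {
  expect_equal(nmdar:::quantize_intervals(c(1, 2.4, 2.5, 7.4, 7.5, 12), 5),
               c(5, 5, 5, 5, 10, 10))
  expect_equal(nmdar:::quantize_intervals(c(13, 17.5), 5), c(15, 20))
})

teacher <- build_scheme("optimized")

test_that("look-up amplitudes are reproducible teacher peaks (memoization)", {
  model <- build_lut(teacher, M = 1000, delta = 5)
  a1 <- lut_amplitude(model, 1)
  expect_gt(a1, 0); expect_lt(a1, 1)
  # single-pulse entry equals the teacher's single-release peak
  sim <- simulate_scheme(teacher, synaptic_transient(0, glycine = 20), 50,
                         dt = 0.1)
  expect_equal(a1, max(sim$open_probability), tolerance = 1e-9)
  # memoized entry identical to a fresh teacher computation
  a2 <- lut_amplitude(model, 2, 100)
  expect_equal(a2, nmdar:::teacher_peak(model, 100), tolerance = 1e-9)
  # an interval as long as the memory window nearly forgets the first pulse
  a_far <- lut_amplitude(model, 2, 1000)
  expect_lt(abs(a_far - a1) / a1, 0.02)
  expect_error(lut_amplitude(model, 3, 50), "requires 2 intervals")
})

test_that("exhaustive enumeration respects the budget and small configs", {
  small <- build_lut(teacher, M = 15, delta = 5, max_order = 3,
                     mode = "exhaustive")
  # tuples: (), (5),(10),(15), (5,5),(5,10),(10,5)
  expect_equal(length(ls(small$table)), 7L)
  expect_error(build_lut(teacher, M = 1000, delta = 5, max_order = 5,
                         mode = "exhaustive", entry_budget = 1000),
               "on_demand")
})

test_that("predictions scale the basis by stored amplitudes and cap the order", {
  basis <- lapply(1:5, function(o) basis_params(4, 50, 220))
  model <- build_lut(teacher, basis = basis, M = 1000, delta = 5)
  # single event: amplitude x basis waveform exactly
  pred <- lut_predict(model, 0, duration = 400, dt = 0.5)
  a1 <- lut_amplitude(model, 1)
  expect_equal(pred$open_probability,
               a1 * basis_waveform(pred$time, basis[[1]]))
  # empty train: zero trace
  none <- lut_predict(model, numeric(0), duration = 100, dt = 1)
  expect_equal(none$open_probability, rep(0, length(none$time)))
  # only the five most recent events matter: perturb the 6th-oldest.
  # Amplitudes depend only on the 5-event pattern under either rule; the
  # supersede trace is exactly invariant once the perturbed event's own
  # window has passed.
  ev <- c(0, 30, 60, 90, 120, 150, 180)
  ev2 <- c(5, 30, 60, 90, 120, 150, 180)
  p1 <- lut_predict(model, ev, duration = 600, dt = 1, rule = "supersede")
  p2 <- lut_predict(model, ev2, duration = 600, dt = 1, rule = "supersede")
  after <- p1$time >= 150
  expect_equal(p1$open_probability[after], p2$open_probability[after])
  a1 <- lut_predict(model, ev, duration = 600, dt = 1)
  a2_ <- lut_predict(model, ev2, duration = 600, dt = 1)
  expect_equal(a1$amplitudes[7], a2_$amplitudes[7])  # last event: 5-pattern identical
  # two-event prediction peak equals the stored order-2 amplitude
  pred2 <- lut_predict(model, c(0, 100), duration = 600, dt = 0.5,
                       rule = "supersede")
  a2 <- lut_amplitude(model, 2, 100)
  seg <- pred2$open_probability[pred2$time >= 100]
  expect_equal(max(seg), a2, tolerance = 0.01)
  # additive rule reaches the same stored amplitude within basis-fit error
  pred2a <- lut_predict(model, c(0, 100), duration = 600, dt = 0.5)
  expect_equal(max(pred2a$open_probability[pred2a$time >= 100]), a2,
               tolerance = 0.05)
})

test_that("mean order responses require enough instances per order", {
  ev <- c(0, 100, 200, 2000, 2100, 2200, 4000, 4100, 4300)
  stim <- synaptic_transient(ev, glycine = 20)
  sim <- simulate_scheme(teacher, stim, 5000, dt = 0.5)
  expect_error(
    mean_order_responses(sim$time, sim$open_probability, ev, M = 1000),
    "too few instances")
  mr <- mean_order_responses(sim$time, sim$open_probability, ev, M = 1000,
                             max_order = 3)
  expect_equal(vapply(mr, `[[`, numeric(1), "n"), c(3, 3, 3))
  # segments are unit-normalized before averaging; slight peak-time jitter
  # across instances can only lower the mean's peak marginally
  for (o in 1:3) {
    expect_lte(max(mr[[o]]$mean), 1)
    expect_gt(max(mr[[o]]$mean), 0.97)
  }
})

test_that("basis fitting recovers a known generating triplet", {
  truth <- c(4, 45, 230)
  bp <- basis_params(truth[1], truth[2], truth[3])
  tt <- seq(0, 900, by = 0.5)
  target <- basis_waveform(tt, bp)
  fit <- fit_basis_to_waveform(tt, target,
                               config = pso_config(50, 200, seed = 1))
  got <- c(fit$params$Tc1, fit$params$Tc2, fit$params$Tc3)
  expect_true(all(abs(got - truth) / truth < 0.05))
  # optimum at least as good as the truth itself
  expect_lte(fit$loss, 1e-3)
})

test_that("LUT models round-trip through JSON exactly", {
  basis <- lapply(1:5, function(o) basis_params(4 + o, 50, 220))
  model <- build_lut(teacher, basis = basis, M = 1000, delta = 5)
  invisible(lut_amplitude(model, 2, 55))
  invisible(lut_amplitude(model, 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_lut(model, path)
  back <- read_lut(path)
  expect_equal(back$M, model$M)
  expect_equal(back$delta, model$delta)
  expect_equal(sort(ls(back$table)), sort(ls(model$table)))
  for (k in ls(model$table))
    expect_equal(back$table[[k]], model$table[[k]])
  expect_equal(back$basis[[3]]$Tc1, model$basis[[3]]$Tc1)
  expect_equal(unclass(back$teacher$rates), unclass(model$teacher$rates))
  # predictions from the restored model are identical
  p1 <- lut_predict(model, c(0, 55), duration = 300, dt = 1)
  p2 <- lut_predict(back, c(0, 55), duration = 300, dt = 1)
  expect_equal(p2$open_probability, p1$open_probability)
})
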