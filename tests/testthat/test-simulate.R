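test_that("occupancies stay in [0,1] and conserve probability on all protocols", {
  sch <- build_scheme("optimized")
  sims <- list(
    simulate_scheme(sch, square_pulse_train(10, 3, 1, 1000), 300, dt = 0.05),
    simulate_scheme(sch, square_pulse_train(100, 3, 1, 1000), 100, dt = 0.05),
    simulate_scheme(sch, synaptic_transient(c(0, 50, 55), glycine = 20), 400,
                    dt = 0.1),
    simulate_scheme(sch, constant_stimulus(1000, 100), 100, dt = 0.1)
  )
  for (sim in sims) {
    expect_true(all(sim$occupancies >= 0 & sim$occupancies <= 1))
    expect_lt(max(abs(rowSums(sim$occupancies) - 1)), 1e-6)
    expect_equal(sim$open_probability,
                 rowSums(sim$occupancies[, c("O1", "O2")]))
  }
})

test_that("open probability is identically zero without glutamate", {
  for (preset in c("original", "optimized")) {
    sch <- build_scheme(preset)
    sim <- simulate_scheme(sch, constant_stimulus(0, 100), 500, dt = 0.5)
    expect_lt(max(sim$open_probability), 1e-9)
  }
})

test_that("constant-ligand simulation matches the matrix-exponential oracle", {
  sch <- build_scheme("optimized")
  concs <- list(c(glu = 1000, gly = 100), c(glu = 50, gly = 20),
                c(glu = 5, gly = 5))
  for (cc in concs) {
    stim <- constant_stimulus(cc["glu"], cc["gly"])
    p0 <- equilibrium_occupancy(sch, cc["gly"])
    sim <- simulate_scheme(sch, stim, 50, dt = 5)
    Q <- generator_matrix(sch, cc["glu"], cc["gly"])
    for (tt in c(5, 25, 50)) {
      ref <- expm_solution(Q, p0, tt)
      got <- sim$occupancies[match(tt, sim$time), ]
      expect_lt(max(abs(got - ref)), 1e-6)
    }
  }
})

test_that("sustained ligand drives occupancies to the generator null space", {
  sch <- build_scheme("optimized")
  stim <- constant_stimulus(1000, 100)
  sim <- simulate_scheme(sch, stim, 5000, dt = 10)
  Q <- generator_matrix(sch, 1000, 100)
  pi_stat <- qr.solve(rbind(Q, rep(1, 9)), c(rep(0, 9), 1))
  final <- sim$occupancies[nrow(sim$occupancies), ]
  expect_lt(max(abs(final - pi_stat)), 1e-6)
})

test_that("brief-pulse peak matches a fine-step explicit reference integration", {
  sch <- build_scheme("optimized")
  stim <- square_pulse_train(10, 1, 1, 1000, glycine = 100)
  sim <- simulate_scheme(sch, stim, 20, dt = 0.01)
  p0 <- equilibrium_occupancy(sch, 100)
  Qfun <- function(t) generator_matrix(sch, if (t < 1) 1000 else 0, 100)
  # RK4 at 0.1 us steps over the pulse, then 1 us to 20 ms
  p_pulse <- rk4_integrate(Qfun, p0, 1, 1e-4)
  ref_grid <- seq(1, 20, by = 0.5)
  Q_off <- generator_matrix(sch, 0, 100)
  op_ref <- vapply(ref_grid, function(tt) {
    p <- expm_solution(Q_off, p_pulse, tt - 1)
    sum(p[match(c("O1", "O2"), sch$states)])
  }, numeric(1))
  peak_ref <- max(op_ref)
  peak_sim <- max(sim$open_probability)
  expect_lt(abs(peak_sim - peak_ref), 1e-4)
})

test_that("open probability collapses after glutamate removal for both presets", {
  for (preset in c("original", "optimized")) {
    sch <- build_scheme(preset)
    sim <- simulate_scheme(sch, square_pulse_train(10, 1, 1, 1000), 4000,
                           dt = 1)
    late <- sim$open_probability[sim$time >= 3500]
    expect_lt(max(late), 1e-6)
  }
})

test_that("simulation rejects invalid durations and initial conditions", {
  sch <- build_scheme("optimized")
  stim <- constant_stimulus(0, 20)
  expect_error(simulate_scheme(sch, stim, -5), "duration")
  expect_error(simulate_scheme(sch, stim, 10, init = rep(0.5, 9)), "sum to 1")
})
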