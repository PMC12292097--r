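# Independent oracles used across the suite.

# Brute-force fixed-step RK4 integration of dp/dt = Q(t) p, independent of
# the package's propagators.
rk4_integrate <- function(Qfun, p0, t_end, dt) {
  n <- ceiling(t_end / dt)
  p <- p0
  t <- 0
  for (i in seq_len(n)) {
    k1 <- Qfun(t) %*% p
    k2 <- Qfun(t + dt / 2) %*% (p + dt / 2 * k1)
    k3 <- Qfun(t + dt / 2) %*% (p + dt / 2 * k2)
    k4 <- Qfun(t + dt) %*% (p + dt * k3)
    p <- p + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
  }
  as.numeric(p)
}

# Matrix exponential solution p(t) = expm(Q t) p0 via the Matrix package
# (independent of the package's eigendecomposition propagator).
expm_solution <- function(Q, p0, t) {
  as.numeric(Matrix::expm(Matrix::Matrix(Q * t)) %*% p0)
}

# Stationary distribution of a generator by brute-force long-time
# propagation.
stationary_by_propagation <- function(Q, p0, t_long = 1e5) {
  expm_solution(Q, p0, t_long)
}
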