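# Conductance and current: open probability -> single-channel conductance
# (with the voltage-dependent Mg2+ block) -> population EPSC.

#' Voltage-dependent magnesium block factor
#'
#' Fraction of the Mg-free single-channel conductance that survives the
#' voltage-dependent Mg2+ block of the pore:
#' \deqn{B(V) = 1 / (1 + ([Mg]_o / K_0) e^{-0.062 V})}
#' Strictly increasing in V, strictly decreasing in [Mg]_o, and equal to 1
#' without magnesium.
#'
#' @param V Membrane potential (mV); vectorized.
#' @param Mg_o External magnesium concentration (mM), non-negative.
#' @param K0 Magnesium equilibrium constant (dimensionless), default 3.57.
#' @return Block factor in (0, 1].
#' @examples
#' mg_block_factor(0, 3.57)    # 0.5
#' mg_block_factor(-100, 0)    # 1
#' @export
mg_block_factor <- function(V, Mg_o, K0 = 3.57) {
  if (K0 <= 0) stop("K0 must be positive")
  if (any(Mg_o < 0)) stop("Mg_o must be non-negative")
  1 / (1 + (Mg_o / K0) * exp(-0.062 * V))
}

#' Magnesium-free single-channel conductance
#'
#' Logistic interpolation between the two open-state conductances as a
#' function of the holding potential:
#' \deqn{g_0 = g_1 + (g_2 - g_1) / (1 + e^{\alpha \Psi_m})}
#' Always lies between \code{g1} and \code{g2}.
#'
#' @param g1,g2 Open-state conductances (pS), non-negative.
#' @param alpha Voltage steepness (mV^-1).
#' @param Psi_m Holding potential (mV); vectorized.
#' @return Conductance (pS).
#' @export
g0_conductance <- function(g1, g2, alpha, Psi_m) {
  if (g1 < 0 || g2 < 0) stop("conductances must be non-negative")
  g1 + (g2 - g1) / (1 + exp(alpha * Psi_m))
}

#' Conductance and driving-force parameters for EPSC conversion
#'
#' The g1/g2/alpha defaults are configuration placeholders on the order of
#' reported NMDA-R subconductances; all normalized quantities in this
#' package (normalized EPSC traces, I-V percentages, decay constants) are
#' invariant to them.
#'
#' @param N Receptor count (>= 1).
#' @param V Membrane potential (mV).
#' @param Vrev Reversal potential (mV), default 0.
#' @param Mg_o External magnesium (mM).
#' @param K0 Magnesium equilibrium constant, default 3.57.
#' @param g1,g2 Open-state conductances (pS).
#' @param alpha Voltage steepness (mV^-1).
#' @param Psi_m Holding potential (mV); defaults to \code{V}.
#' @return A \code{conductance_params} list.
#' @export
conductance_params <- function(N = 100, V = -100, Vrev = 0, Mg_o = 0,
                               K0 = 3.57, g1 = 40, g2 = 247, alpha = 0.01,
                               Psi_m = V) {
  if (N < 1) stop("N must be >= 1")
  if (Mg_o < 0) stop("Mg_o must be non-negative")
  if (K0 <= 0) stop("K0 must be positive")
  structure(list(N = N, V = V, Vrev = Vrev, Mg_o = Mg_o, K0 = K0,
                 g1 = g1, g2 = g2, alpha = alpha, Psi_m = Psi_m),
            class = "conductance_params")
}

#' EPSC from an open-probability time series
#'
#' \deqn{I(t) = N (V - V_{rev}) g_{max} O(t)} with
#' \eqn{g_{max} = g_0 B(V)}: the population current is linear in receptor
#' count and driving force, and strictly proportional to open probability.
#' With conductance in pS and potential in mV the current is returned in pA.
#'
#' @param result An \code{nmdar_sim} or a numeric open-probability series.
#' @param params A \code{\link{conductance_params}}.
#' @return Numeric current series (pA).
#' @export
epsc <- function(result, params) {
  stopifnot(inherits(params, "conductance_params"))
  op <- if (inherits(result, "nmdar_sim")) result$open_probability
        else as.numeric(result)
  g0 <- g0_conductance(params$g1, params$g2, params$alpha, params$Psi_m)
  gmax <- g0 * mg_block_factor(params$V, params$Mg_o, params$K0)
  # pS * mV = fA; 1e-3 converts to pA
  params$N * (params$V - params$Vrev) * gmax * op * 1e-3
}

#' Current-voltage relationship of the peak synaptic EPSC
#'
#' Simulates the synaptic response once (state kinetics do not depend on
#' voltage; the Mg2+ block acts on conductance), converts to current at
#' each holding potential with \eqn{\Psi_m = V}, records the signed peak
#' (the extremum of largest magnitude), and reports each peak as a percent
#' of the +40 mV peak. With 1 mM Mg2+ the curve shows the characteristic
#' negative-slope region at negative potentials.
#'
#' @param scheme A \code{kinetic_scheme}.
#' @param stimulus Synaptic stimulus (see \code{\link{synaptic_transient}}).
#' @param params Base \code{conductance_params}; \code{V}, \code{Psi_m}
#'   are swept over \code{V_grid}.
#' @param V_grid Holding potentials (mV); must contain +40.
#' @param duration Simulated time (ms).
#' @param dt Reporting step (ms).
#' @return Data frame with columns \code{V_mV}, \code{peak_pA},
#'   \code{percent_of_40mV}.
#' @export
iv_curve <- function(scheme, stimulus, params, V_grid,
                     duration = 500, dt = 0.1) {
  if (!any(abs(V_grid - 40) < 1e-9))
    stop("V_grid must contain +40 mV (the normalization point)")
  sim <- simulate_scheme(scheme, stimulus, duration, dt = dt)
  peak_op <- max(sim$open_probability)
  peaks <- vapply(V_grid, function(v) {
    p <- params
    p$V <- v
    p$Psi_m <- v
    i <- epsc(peak_op, p)
    i
  }, numeric(1))
  ref <- peaks[which(abs(V_grid - 40) < 1e-9)[1]]
  if (abs(ref) < .Machine$double.eps)
    stop("peak EPSC at +40 mV is zero; cannot normalize")
  data.frame(V_mV = V_grid,
             peak_pA = peaks,
             percent_of_40mV = 100 * peaks / ref)
}
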