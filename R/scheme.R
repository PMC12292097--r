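# Nine-state kinetic scheme of GluN1/GluN2A NMDA-R.
#
# Default topology ("glycine-desensitization"):
#
#   S1 (apo) = S2 (1 Glu) = C3 (2 Glu) = C2 = C1 = O1 = O2
#                            ||
#                            D1 (C3 minus 1 Gly) = D2 (C3 minus 2 Gly)
#
# The classic sequential activation chain (two glutamate-binding steps, three
# diliganded closed states, two open states) is augmented with two
# glycine-depleted states branching off the first diliganded closed
# state: once glutamate is bound, glycine can dissociate, leaving the
# receptor desensitized with glutamate trapped until glycine rebinds
# (glycine-dependent desensitization). At sub-saturating glycine this
# branch produces the slow component of the synaptic decay.
#
# The alternative "sequential" topology places the glycine steps at the
# front of a pure chain:
#   S1 (apo) = S2 (1 Gly) = S3 (2 Gly) = S4 (+1 Glu) = C3 (+2 Glu)
#     = C2 = C1 = O1 = O2
# Both have 9 states and 8 reversible transition pairs.

#' State labels of the nine-state scheme (default topology)
#' @format Character vector of length 9.
#' @export
STATE_NAMES <- c("S1", "S2", "C3", "C2", "C1", "O1", "O2", "D1", "D2")

#' Build the nine-state kinetic scheme
#'
#' Assembles the kinetic scheme and precomputes the generator-matrix
#' decomposition \eqn{Q(glu, gly) = Q0 + [Glu] Qglu + [Gly] Qgly} used by
#' the ODE right-hand side and the piecewise-exact propagator. Internally
#' all rates are converted to ms^-1 with ligand concentrations in uM.
#'
#' @param rates A \code{\link{rate_constants}} object or preset name.
#' @param statistical_factors Binding-site statistical factor convention:
#'   \code{"none"} (default; the tabulated rates are effective
#'   per-transition rates) or \code{"paired-sites"} (2x forward on the
#'   first of two identical-site binding steps, 2x reverse on the second).
#' @param topology \code{"glycine-desensitization"} (default): glycine
#'   dissociates from the diliganded closed state into desensitized
#'   states; \code{"sequential"}: pure chain with glycine binding before
#'   glutamate.
#' @return An object of class \code{kinetic_scheme} with elements
#'   \code{states}, \code{open_states}, \code{transitions} (data frame of
#'   directed transitions), \code{rates}, and the matrices \code{Q0},
#'   \code{Qglu}, \code{Qgly}.
#' @examples
#' sch <- build_scheme("optimized")
#' nrow(sch$transitions)  # 16 directed transitions (8 reversible pairs)
#' @export
build_scheme <- function(rates,
                         statistical_factors = c("none", "paired-sites"),
                         topology = c("glycine-desensitization",
                                      "sequential")) {
  rates <- rate_constants(rates)
  statistical_factors <- match.arg(statistical_factors)
  topology <- match.arg(topology)
  f <- if (statistical_factors == "paired-sites") 2 else 1

  r <- unclass(rates) / 1000  # s^-1 -> ms^-1 (and uM^-1 s^-1 -> uM^-1 ms^-1)

  edge <- function(from, to, rate, ligand = "none")
    data.frame(from = from, to = to, rate = unname(rate), ligand = ligand,
               stringsAsFactors = FALSE)
  gating <- rbind(
    edge("C3", "C2", r["k32"]),   edge("C2", "C3", r["k23"]),
    edge("C2", "C1", r["k21"]),   edge("C1", "C2", r["k12"]),
    edge("C1", "O1", r["k1_O1"]), edge("O1", "C1", r["kO1_1"]),
    edge("O1", "O2", r["kO1_O2"]), edge("O2", "O1", r["kO2_O1"]))

  if (topology == "glycine-desensitization") {
    states <- STATE_NAMES
    tr <- rbind(
      edge("S1", "S2", f * r["kon"], "glu"),  edge("S2", "S1", r["koff"]),
      edge("S2", "C3", r["kon"], "glu"),      edge("C3", "S2", f * r["koff"]),
      gating,
      edge("C3", "D1", f * r["kgly_off"]),
      edge("D1", "C3", r["kgly_on"], "gly"),
      edge("D1", "D2", r["kgly_off"]),
      edge("D2", "D1", f * r["kgly_on"], "gly"))
  } else {
    states <- c("S1", "S2", "S3", "S4", "C3", "C2", "C1", "O1", "O2")
    tr <- rbind(
      edge("S1", "S2", f * r["kgly_on"], "gly"), edge("S2", "S1", r["kgly_off"]),
      edge("S2", "S3", r["kgly_on"], "gly"), edge("S3", "S2", f * r["kgly_off"]),
      edge("S3", "S4", f * r["kon"], "glu"), edge("S4", "S3", r["koff"]),
      edge("S4", "C3", r["kon"], "glu"),     edge("C3", "S4", f * r["koff"]),
      gating)
  }

  n <- length(states)
  Q0 <- Qglu <- Qgly <- matrix(0, n, n, dimnames = list(states, states))
  for (i in seq_len(nrow(tr))) {
    a <- tr$from[i]; b <- tr$to[i]; k <- tr$rate[i]
    M <- switch(tr$ligand[i], none = "Q0", glu = "Qglu", gly = "Qgly")
    m <- get(M)
    m[b, a] <- m[b, a] + k
    m[a, a] <- m[a, a] - k
    assign(M, m)
  }

  structure(list(states = states,
                 open_states = c("O1", "O2"),
                 transitions = tr,
                 rates = rates,
                 statistical_factors = statistical_factors,
                 topology = topology,
                 Q0 = Q0, Qglu = Qglu, Qgly = Qgly),
            class = "kinetic_scheme")
}

#' Generator matrix at fixed ligand concentrations
#'
#' @param scheme A \code{kinetic_scheme}.
#' @param glutamate,glycine Ligand concentrations (uM), non-negative.
#' @return 9x9 generator matrix Q (ms^-1) such that dp/dt = Q p; columns
#'   sum to zero.
#' @export
generator_matrix <- function(scheme, glutamate, glycine) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (glutamate < 0 || glycine < 0)
    stop("ligand concentrations must be non-negative")
  scheme$Q0 + glutamate * scheme$Qglu + glycine * scheme$Qgly
}

#' ODE right-hand side of the kinetic scheme
#'
#' First-order mass-action kinetics of the state occupancies: for fixed
#' ligand concentrations the derivative is the generator matrix applied to
#' the occupancy vector, so the derivatives always sum to zero
#' (probability conservation).
#'
#' @param occupancy Numeric 9-vector of state occupancies.
#' @param t Time (ms); only used to evaluate time-dependent signals.
#' @param glutamate,glycine Concentration (uM): a scalar or a function of
#'   time returning uM.
#' @param scheme A \code{kinetic_scheme}.
#' @return Numeric 9-vector of occupancy derivatives (ms^-1).
#' @export
ode_rhs <- function(occupancy, t = 0, glutamate, glycine, scheme) {
  glu <- if (is.function(glutamate)) glutamate(t) else glutamate
  gly <- if (is.function(glycine)) glycine(t) else glycine
  Q <- generator_matrix(scheme, glu, gly)
  unname(drop(Q %*% occupancy))
}

#' Resting occupancy at zero glutamate
#'
#' Stationary distribution of the scheme without glutamate, at the given
#' tonic glycine concentration. In the default topology every receptor
#' rests in the apo state S1 (glycine-depleted states are only reachable
#' after glutamate binds); in the sequential topology the glycine-binding
#' sub-chain S1/S2/S3 equilibrates. Used as the default initial condition.
#'
#' @param scheme A \code{kinetic_scheme}.
#' @param glycine Glycine concentration (uM), strictly positive.
#' @return Named occupancy 9-vector summing to 1.
#' @export
equilibrium_occupancy <- function(scheme, glycine) {
  if (glycine <= 0)
    stop("tonic glycine must be positive for a unique resting state")
  Q <- generator_matrix(scheme, 0, glycine)
  A <- rbind(Q, rep(1, ncol(Q)))
  b <- c(rep(0, nrow(Q)), 1)
  p <- qr.solve(A, b)
  p[abs(p) < 1e-14] <- 0
  p <- pmax(p, 0)
  p <- p / sum(p)
  names(p) <- scheme$states
  p
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Nine-state NMDA-R kinetic scheme (", x$topology, ", ",
      x$statistical_factors, " statistical factors)\n", sep = "")
  cat("States:", paste(x$states, collapse = " "), "\n")
  cat("Open states:", paste(x$open_states, collapse = ", "), "\n")
  invisible(x)
}
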