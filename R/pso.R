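# Global-best particle swarm optimization.
#
# Canonical velocity update
#   v <- w*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)
# with per-dimension uniform r1, r2, positions clamped to the box bounds
# and velocities clamped to half the bound range. Non-finite objective
# values cull the particle for that evaluation (treated as +Inf).

#' Particle swarm optimization configuration
#'
#' @param n_particles Swarm size.
#' @param n_generations Number of generations (fixed-count stopping).
#' @param inertia Velocity weight (default 0.5).
#' @param cognitive_rate Weight of the particle's personal best (default 2.1).
#' @param social_rate Weight of the global best (default 2.1).
#' @param seed Integer seed for reproducibility.
#' @param n_trials Independent restarts; trial t uses seed + t - 1 and the
#'   best solution across trials is returned.
#' @param init \code{"uniform"} or \code{"log-uniform"} initialization of
#'   positions within the bounds (log-uniform suits rate constants
#'   spanning decades; requires positive bounds).
#' @return A \code{pso_config} list.
#' @export
pso_config <- function(n_particles = 50, n_generations = 200,
                       inertia = 0.5, cognitive_rate = 2.1,
                       social_rate = 2.1, seed = 1, n_trials = 1,
                       init = c("uniform", "log-uniform")) {
  stopifnot(n_particles >= 1, n_generations >= 1, n_trials >= 1)
  structure(list(n_particles = n_particles, n_generations = n_generations,
                 inertia = inertia, cognitive_rate = cognitive_rate,
                 social_rate = social_rate, seed = seed,
                 n_trials = n_trials, init = match.arg(init)),
            class = "pso_config")
}

#' Minimize an objective with particle swarm optimization
#'
#' @param objective Function mapping a parameter vector to a scalar loss.
#'   Non-finite returns are treated as +Inf (the particle is culled for
#'   that generation).
#' @param lower,upper Box bounds per parameter (lower < upper).
#' @param config A \code{\link{pso_config}}.
#' @param init_points Optional numeric matrix (rows = candidate parameter
#'   vectors) used to warm-start the swarm: the first rows of the initial
#'   population are replaced by these points (clamped to the bounds).
#'   Useful when moment-matched heuristics suggest a starting basin.
#' @param verbose Print per-generation best loss.
#' @return List with \code{par} (best parameters), \code{value} (best
#'   loss), \code{history} (best-so-far loss per generation of the winning
#'   trial), and \code{trials} (per-trial best values).
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- pso_optimize(sphere, c(-5, -5), c(5, 5),
#'                     pso_config(30, 100, seed = 1))
#' res$value < 1e-4
#' @export
pso_optimize <- function(objective, lower, upper, config = pso_config(),
                         init_points = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pso_config"))
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != length(upper) || any(lower >= upper))
    stop("bounds must satisfy lower < upper per parameter")
  d <- length(lower)

  run_trial <- function(seed) {
    with_preserved_seed(seed, {
      np <- config$n_particles
      rng <- upper - lower
      if (config$init == "log-uniform") {
        if (any(lower <= 0))
          stop("log-uniform initialization requires positive lower bounds")
        X <- exp(matrix(stats::runif(np * d, log(lower), log(upper)),
                        np, d, byrow = TRUE))
      } else {
        X <- matrix(stats::runif(np * d, lower, upper), np, d, byrow = TRUE)
      }
      if (!is.null(init_points)) {
        ip <- matrix(as.numeric(init_points), ncol = d)
        k <- min(nrow(ip), np)
        X[seq_len(k), ] <- pmin(pmax(ip[seq_len(k), , drop = FALSE],
                                     matrix(lower, k, d, byrow = TRUE)),
                                matrix(upper, k, d, byrow = TRUE))
      }
      Vel <- matrix(stats::runif(np * d, -rng / 2, rng / 2), np, d,
                    byrow = TRUE)
      evals <- apply(X, 1, function(x) {
        v <- tryCatch(objective(x), error = function(e) Inf)
        if (!is.finite(v)) Inf else v
      })
      if (all(!is.finite(evals)))
        stop("all particles returned non-finite loss in the initial ",
             "generation; check bounds/objective")
      Pbest <- X
      pval <- evals
      g <- which.min(pval)
      gbest <- X[g, ]; gval <- pval[g]
      history <- numeric(config$n_generations)
      vmax <- rng / 2
      for (gen in seq_len(config$n_generations)) {
        r1 <- matrix(stats::runif(np * d), np, d)
        r2 <- matrix(stats::runif(np * d), np, d)
        Vel <- config$inertia * Vel +
          config$cognitive_rate * r1 * (Pbest - X) +
          config$social_rate * r2 * (matrix(gbest, np, d, byrow = TRUE) - X)
        Vel <- pmin(pmax(Vel, matrix(-vmax, np, d, byrow = TRUE)),
                    matrix(vmax, np, d, byrow = TRUE))
        X <- X + Vel
        X <- pmin(pmax(X, matrix(lower, np, d, byrow = TRUE)),
                  matrix(upper, np, d, byrow = TRUE))
        evals <- apply(X, 1, function(x) {
          v <- tryCatch(objective(x), error = function(e) Inf)
          if (!is.finite(v)) Inf else v
        })
        if (all(!is.finite(evals)))
          stop("all particles returned non-finite loss at generation ", gen)
        imp <- evals < pval
        Pbest[imp, ] <- X[imp, , drop = FALSE]
        pval[imp] <- evals[imp]
        g <- which.min(pval)
        if (pval[g] < gval) {
          gval <- pval[g]
          gbest <- Pbest[g, ]
        }
        history[gen] <- gval
        if (verbose)
          message(sprintf("generation %d: best loss %.6g", gen, gval))
      }
      list(par = gbest, value = gval, history = history)
    })
  }

  trials <- lapply(seq_len(config$n_trials),
                   function(tr) run_trial(config$seed + tr - 1L))
  vals <- vapply(trials, `[[`, numeric(1), "value")
  best <- which.min(vals)
  out <- trials[[best]]
  out$trials <- vals
  out
}
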