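# Calibration of the rate constants: the three stimulation protocols, the
# composite loss (trace NRMSE + relative peak errors), self-calibration
# target generation, and the PSO-driven fit.

#' The three calibration protocols
#'
#' Protocols used to constrain the kinetic model:
#' \enumerate{
#'   \item three 1 ms square pulses of 1 mM glutamate at 10 Hz
#'     (0.1 mM glycine, 0 Mg, -100 mV),
#'   \item the same at 100 Hz,
#'   \item a single synaptic glutamate release
#'     (0.02 mM glycine, 1 mM Mg, +40 mV).
#' }
#' Peak open probabilities are recorded from the square trains; the
#' normalized EPSC trace from the synaptic protocol.
#'
#' @param syn_duration Synaptic simulation length (ms).
#' @param train_dt,syn_dt Reporting steps (ms).
#' @return A list of protocol descriptions used by
#'   \code{\link{make_calibration_targets}} and
#'   \code{\link{calibration_loss}}.
#' @export
calibration_protocols <- function(syn_duration = 1000, train_dt = 0.01,
                                  syn_dt = 0.1) {
  list(
    hz10 = list(stimulus = square_pulse_train(10, 3, 1, 1000, glycine = 100),
                duration = 300, dt = train_dt,
                pulse_times = c(0, 100, 200)),
    hz100 = list(stimulus = square_pulse_train(100, 3, 1, 1000, glycine = 100),
                 duration = 100, dt = train_dt,
                 pulse_times = c(0, 10, 20)),
    synaptic = list(stimulus = synaptic_transient(0, glycine = 20),
                    duration = syn_duration, dt = syn_dt,
                    cond = conductance_params(V = 40, Mg_o = 1))
  )
}

run_calibration_protocols <- function(theta, protocols,
                                      statistical_factors = "none") {
  scheme <- build_scheme(theta, statistical_factors)
  s10 <- simulate_scheme(scheme, protocols$hz10$stimulus,
                         protocols$hz10$duration, dt = protocols$hz10$dt)
  s100 <- simulate_scheme(scheme, protocols$hz100$stimulus,
                          protocols$hz100$duration, dt = protocols$hz100$dt)
  ssyn <- simulate_scheme(scheme, protocols$synaptic$stimulus,
                          protocols$synaptic$duration,
                          dt = protocols$synaptic$dt)
  isyn <- epsc(ssyn, protocols$synaptic$cond)
  list(peaks_10Hz = suppressWarnings(
         detect_peaks(s10$time, s10$open_probability,
                      protocols$hz10$pulse_times)),
       peaks_100Hz = suppressWarnings(
         detect_peaks(s100$time, s100$open_probability,
                      protocols$hz100$pulse_times)),
       trace_time = ssyn$time,
       trace = normalize_trace(isyn),
       sims = list(hz10 = s10, hz100 = s100, synaptic = ssyn))
}

#' Generate self-calibration targets from known rate constants
#'
#' Runs the three calibration protocols with a known parameter set and
#' packages the resulting peak open probabilities and normalized synaptic
#' EPSC trace as calibration targets, optionally corrupted with
#' multiplicative Gaussian noise. Used for parameter-recovery experiments
#' when no experimental target set is supplied.
#'
#' @param theta Rate constants (object or preset name).
#' @param noise_level Relative standard deviation of multiplicative noise
#'   (0 = noiseless).
#' @param seed Seed for the noise draw.
#' @param protocols Output of \code{\link{calibration_protocols}}.
#' @param statistical_factors Scheme convention (see
#'   \code{\link{build_scheme}}).
#' @return Object of class \code{calibration_targets}: \code{peaks_10Hz},
#'   \code{peaks_100Hz}, \code{trace_time}, \code{trace}.
#' @export
make_calibration_targets <- function(theta, noise_level = 0, seed = NULL,
                                     protocols = calibration_protocols(),
                                     statistical_factors = "none") {
  theta <- rate_constants(theta)
  res <- run_calibration_protocols(theta, protocols, statistical_factors)
  tg <- list(peaks_10Hz = res$peaks_10Hz,
             peaks_100Hz = res$peaks_100Hz,
             trace_time = res$trace_time,
             trace = res$trace)
  if (noise_level > 0) {
    noisy <- function(x, n) x * (1 + noise_level * stats::rnorm(length(x)))
    apply_noise <- function() {
      tg$peaks_10Hz <<- abs(noisy(tg$peaks_10Hz))
      tg$peaks_100Hz <<- abs(noisy(tg$peaks_100Hz))
      tg$trace <<- normalize_trace(noisy(tg$trace))
    }
    if (is.null(seed)) apply_noise() else with_preserved_seed(seed, apply_noise())
  }
  tg$generator <- list(theta = unclass(theta), noise_level = noise_level,
                       seed = seed)
  structure(tg, class = "calibration_targets")
}

#' Composite calibration loss
#'
#' \deqn{J(\theta) = \tfrac12 NRMSE(i_{syn}, \hat i_{syn}(\theta))
#'   + 0.1 \sum_{i=1}^{3} |p_{i,10} - \hat p_{i,10}| / p_{i,10}
#'   + 0.1 \sum_{i=2}^{3} |p_{i,100} - \hat p_{i,100}| / p_{i,100}}
#' Half the weight is on the normalized synaptic temporal profile, the
#' rest on the relative errors of the peak open probabilities under 10 and
#' 100 Hz trains; the first 100 Hz peak is discarded because it duplicates
#' the first 10 Hz peak. Traces are compared after linear resampling onto
#' a common 1 ms grid. A failed simulation yields +Inf so the particle is
#' culled without stopping an optimization run.
#'
#' @param theta Candidate rate constants (object, preset name, or bare
#'   numeric vector in \code{\link{RATE_NAMES}} order).
#' @param targets A \code{calibration_targets}.
#' @param protocols Protocol list (see \code{\link{calibration_protocols}}).
#' @param statistical_factors Scheme convention.
#' @param loss_grid_dt Common trace-comparison grid step (ms).
#' @return Scalar loss (0 for a perfect match).
#' @export
calibration_loss <- function(theta, targets,
                             protocols = calibration_protocols(),
                             statistical_factors = "none",
                             loss_grid_dt = 1) {
  stopifnot(inherits(targets, "calibration_targets"))
  if (!inherits(theta, "rate_constants") && is.numeric(theta) &&
      is.null(names(theta)))
    theta <- stats::setNames(theta, RATE_NAMES)
  theta <- tryCatch(rate_constants(theta), error = function(e) NULL)
  if (is.null(theta)) return(Inf)
  res <- tryCatch(
    run_calibration_protocols(theta, protocols, statistical_factors),
    error = function(e) NULL)
  if (is.null(res)) return(Inf)

  calibration_loss_parts(targets, res$peaks_10Hz, res$peaks_100Hz,
                         res$trace_time, res$trace, loss_grid_dt)$total
}

# The three weighted loss components from already-computed model outputs:
# 0.5 * trace NRMSE, 0.1 * sum of relative 10 Hz peak errors (all three),
# 0.1 * sum of relative 100 Hz peak errors (first discarded as redundant).
calibration_loss_parts <- function(targets, peaks_10Hz, peaks_100Hz,
                                   trace_time, trace, loss_grid_dt = 1) {
  grid <- seq(0, min(max(targets$trace_time), max(trace_time)),
              by = loss_grid_dt)
  ref <- stats::approx(targets$trace_time, targets$trace, grid)$y
  est <- stats::approx(trace_time, trace, grid)$y
  trace_term <- 0.5 * nrmse(ref, est)
  p10 <- 0.1 * sum(abs(targets$peaks_10Hz - peaks_10Hz) / targets$peaks_10Hz)
  p100 <- 0.1 * sum(abs(targets$peaks_100Hz[2:3] - peaks_100Hz[2:3]) /
                      targets$peaks_100Hz[2:3])
  list(trace = trace_term, peaks_10Hz = p10, peaks_100Hz = p100,
       total = trace_term + p10 + p100)
}

#' Fit the rate constants to calibration targets with PSO
#'
#' @param targets A \code{calibration_targets}.
#' @param config A \code{\link{pso_config}}; log-uniform initialization is
#'   used regardless of \code{config$init} (rates span decades).
#' @param bounds List with numeric vectors \code{lower} and \code{upper}
#'   (length 12, \code{\link{RATE_NAMES}} order); default is 0.1x--10x of
#'   the "original" preset.
#' @param protocols,statistical_factors Passed to
#'   \code{\link{calibration_loss}}.
#' @return List with \code{rates} (fitted \code{rate_constants}),
#'   \code{loss}, \code{history}, \code{trials}.
#' @export
fit_rate_constants <- function(targets, config = pso_config(seed = 1),
                               bounds = NULL,
                               protocols = calibration_protocols(),
                               statistical_factors = "none") {
  if (is.null(bounds)) {
    base <- unclass(rate_constants("original"))
    bounds <- list(lower = 0.1 * base, upper = 10 * base)
  }
  config$init <- "log-uniform"
  obj <- function(x) calibration_loss(x, targets, protocols,
                                      statistical_factors)
  res <- pso_optimize(obj, bounds$lower, bounds$upper, config)
  list(rates = rate_constants(stats::setNames(res$par, RATE_NAMES)),
       loss = res$value, history = res$history, trials = res$trials)
}

#' Read/write calibration targets (CSV trace + JSON peaks)
#'
#' The trace file is a two-column CSV (\code{time_ms},
#' \code{epsc_normalized}); the peaks file a JSON object with arrays
#' \code{peaks_10Hz} and \code{peaks_100Hz}.
#'
#' @param targets A \code{calibration_targets}.
#' @param trace_csv,peaks_json File paths.
#' @return \code{read_calibration_targets} returns a
#'   \code{calibration_targets}.
#' @export
write_calibration_targets <- function(targets, trace_csv, peaks_json) {
  stopifnot(inherits(targets, "calibration_targets"))
  utils::write.csv(data.frame(time_ms = targets$trace_time,
                              epsc_normalized = targets$trace),
                   trace_csv, row.names = FALSE)
  jsonlite::write_json(list(peaks_10Hz = targets$peaks_10Hz,
                            peaks_100Hz = targets$peaks_100Hz),
                       peaks_json, digits = NA)
  invisible(trace_csv)
}

#' @rdname write_calibration_targets
#' @export
read_calibration_targets <- function(trace_csv, peaks_json) {
  tr <- utils::read.csv(trace_csv)
  pk <- jsonlite::read_json(peaks_json, simplifyVector = TRUE)
  structure(list(peaks_10Hz = as.numeric(pk$peaks_10Hz),
                 peaks_100Hz = as.numeric(pk$peaks_100Hz),
                 trace_time = as.numeric(tr[[1]]),
                 trace = as.numeric(tr[[2]])),
            class = "calibration_targets")
}
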