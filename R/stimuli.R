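# Stimulus signals: continuous glutamate (and constant glycine)
# concentration versus time, built from protocol descriptions. A stimulus
# knows how to cut the time axis into segments on which the ligand
# concentrations are either constant (propagated exactly by the simulator)
# or smoothly time-varying (integrated with a stiff ODE solver).

new_stimulus <- function(glu_fun, glycine, breaks, segment_fun, events = NULL,
                         descriptor = list()) {
  structure(list(glu = glu_fun,
                 glycine = glycine,
                 breaks = sort(unique(breaks)),
                 segment_const = segment_fun,  # (t0, t1) -> glu conc or NA
                 events = events,
                 descriptor = descriptor),
            class = "stimulus")
}

#' Square glutamate pulse train
#'
#' Rectangular pulses of glutamate delivered at a fixed frequency, the
#' standard fast-application protocol for probing frequency-dependent
#' potentiation: pulse k occupies \eqn{[k/f, k/f + width)}.
#'
#' @param frequency Pulse rate (Hz).
#' @param n_pulses Number of pulses.
#' @param width Pulse width (ms); must be smaller than the period.
#' @param amplitude Glutamate concentration during a pulse (uM).
#' @param glycine Constant glycine concentration (uM). Default 100 uM
#'   (0.1 mM, saturating).
#' @return A \code{stimulus} object.
#' @examples
#' st <- square_pulse_train(10, 3, 1, 1000)
#' st$glu(0.5)   # 1000
#' st$glu(50)    # 0
#' @export
square_pulse_train <- function(frequency, n_pulses, width, amplitude,
                               glycine = 100) {
  period <- 1000 / frequency
  if (width >= period)
    stop("pulse width (", width, " ms) must be less than the interpulse period (",
         period, " ms)")
  starts <- (seq_len(n_pulses) - 1) * period
  ends <- starts + width
  glu_fun <- function(t) {
    amplitude * vapply(t, function(tt)
      any(tt >= starts & tt < ends), logical(1))
  }
  seg_fun <- function(t0, t1) {
    mid <- (t0 + t1) / 2
    if (any(mid >= starts & mid < ends)) amplitude else 0
  }
  new_stimulus(glu_fun, glycine, breaks = c(starts, ends), seg_fun,
               events = starts,
               descriptor = list(type = "square_train", frequency = frequency,
                                 n_pulses = n_pulses, width = width,
                                 amplitude = amplitude, glycine = glycine))
}

#' Synaptic glutamate release transient
#'
#' Each release event contributes a brief cleft-glutamate transient:
#' instantaneous rise to \code{peak} followed by monoexponential clearance
#' with time constant \code{tau_clear} (optionally a finite exponential
#' rise). Contributions from successive events sum linearly. The defaults
#' (1.1 mM peak, 1.2 ms clearance) are classic estimates of the synaptic
#' cleft glutamate transient after a single vesicle release.
#'
#' @param event_times Sorted, non-negative release times (ms).
#' @param peak Peak concentration per event (uM).
#' @param tau_clear Clearance time constant (ms).
#' @param tau_rise Optional rise time constant (ms); \code{NULL} means an
#'   instantaneous step to \code{peak}.
#' @param glycine Constant glycine concentration (uM). Default 20 uM
#'   (0.02 mM, nominal physiological).
#' @return A \code{stimulus} object.
#' @export
synaptic_transient <- function(event_times, peak = 1100, tau_clear = 1.2,
                               tau_rise = NULL, glycine = 20) {
  if (is.unsorted(event_times) || any(event_times < 0))
    stop("event_times must be sorted and non-negative")
  if (peak <= 0 || tau_clear <= 0)
    stop("peak and tau_clear must be positive")
  ev <- as.numeric(event_times)

  if (is.null(tau_rise)) {
    shape <- function(dt) exp(-dt / tau_clear)
  } else {
    if (tau_rise <= 0 || tau_rise >= tau_clear)
      stop("tau_rise must be positive and smaller than tau_clear")
    # normalized so each event still peaks at `peak`
    tstar <- log(tau_clear / tau_rise) * tau_rise * tau_clear / (tau_clear - tau_rise)
    smax <- exp(-tstar / tau_clear) - exp(-tstar / tau_rise)
    shape <- function(dt) (exp(-dt / tau_clear) - exp(-dt / tau_rise)) / smax
  }
  glu_fun <- function(t) {
    vapply(t, function(tt) {
      d <- tt - ev
      sum(peak * shape(d[d >= 0]))
    }, numeric(1))
  }
  # beyond `cutoff` after the last preceding event the tail is numerically
  # negligible (< 1e-12 of peak) and the segment is treated as glutamate-free
  cutoff <- tau_clear * log(1e12)
  seg_fun <- function(t0, t1) {
    mid <- (t0 + t1) / 2
    if (length(ev) == 0L) return(0)
    prior <- ev[ev <= mid]
    if (length(prior) == 0L) return(0)
    if (mid - max(prior) >= cutoff) 0 else NA_real_
  }
  new_stimulus(glu_fun, glycine, breaks = c(ev, ev + cutoff), seg_fun,
               events = ev,
               descriptor = list(type = "synaptic", peak = peak,
                                 tau_clear = tau_clear, tau_rise = tau_rise,
                                 glycine = glycine, n_events = length(ev)))
}

#' Constant-ligand stimulus
#'
#' @param glutamate,glycine Constant concentrations (uM).
#' @return A \code{stimulus} object.
#' @export
constant_stimulus <- function(glutamate, glycine) {
  if (glutamate < 0 || glycine < 0) stop("concentrations must be non-negative")
  new_stimulus(function(t) rep(glutamate, length(t)), glycine,
               breaks = numeric(0),
               segment_fun = function(t0, t1) glutamate,
               descriptor = list(type = "constant", glutamate = glutamate,
                                 glycine = glycine))
}

#' Homogeneous Poisson event train with refractory spacing
#'
#' Draws event times from a homogeneous Poisson process and thins them so
#' that consecutive events are at least \code{min_spacing} apart (the
#' default matches the look-up-table granularity so quantized intervals
#' are never zero). Reproducible given a seed.
#'
#' @param mean_rate Mean event rate (Hz) of the underlying process.
#' @param duration Train duration (ms).
#' @param seed Integer seed; \code{NULL} uses the current RNG state.
#' @param min_spacing Minimum spacing between retained events (ms).
#' @return Sorted numeric vector of event times (ms).
#' @export
poisson_train <- function(mean_rate, duration, seed = NULL, min_spacing = 5) {
  if (mean_rate <= 0) stop("mean_rate must be positive")
  draw <- function() {
    n_max <- max(20, ceiling(mean_rate * duration / 1000 * 3 + 10))
    gaps <- stats::rexp(n_max, rate = mean_rate / 1000)  # ms
    tt <- cumsum(gaps)
    while (length(tt) && tt[length(tt)] < duration) {
      gaps <- stats::rexp(n_max, rate = mean_rate / 1000)
      tt <- c(tt, tt[length(tt)] + cumsum(gaps))
    }
    tt <- tt[tt < duration]
    keep <- numeric(0)
    last <- -Inf
    for (x in tt) {
      if (x - last >= min_spacing) {
        keep <- c(keep, x)
        last <- x
      }
    }
    keep
  }
  if (is.null(seed)) draw() else with_preserved_seed(seed, draw())
}

# Evaluate `expr` under set.seed(seed) without disturbing the caller's RNG
# stream.
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Cut [0, duration) into simulation segments.
# Returns data.frame(start, end, glu) where glu is NA for time-varying
# segments.
stimulus_segments <- function(stimulus, duration) {
  b <- stimulus$breaks
  b <- b[b > 0 & b < duration]
  bounds <- unique(c(0, b, duration))
  data.frame(start = bounds[-length(bounds)],
             end = bounds[-1],
             glu = vapply(seq_len(length(bounds) - 1L), function(i)
               stimulus$segment_const(bounds[i], bounds[i + 1]), numeric(1)))
}

#' Read or write event times as single-column CSV
#'
#' @param path File path.
#' @param events Numeric event times (ms).
#' @return \code{read_events} returns a numeric vector.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path)
  as.numeric(df[[1]])
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  utils::write.csv(data.frame(time_ms = events), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.stimulus <- function(x, ...) {
  d <- x$descriptor
  cat("Stimulus:", d$type, "| glycine", x$glycine, "uM\n")
  str(d, give.attr = FALSE)
  invisible(x)
}
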