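# LUTsyn: look-up-table surrogate of the kinetic model.
#
# Synaptic responses are categorized by order (1 + number of earlier
# events inside the memory window M, capped at 5). Each order has a
# normalized triple-exponential basis waveform; the look-up table stores
# the teacher model's absolute peak open probability indexed by the
# quantized interpulse intervals of the pattern. A prediction is the
# stored amplitude times the order's basis waveform; the newest event's
# scaled waveform supersedes earlier tails (amplitudes already include
# residual occupancy from the pattern history).

#' Normalization factor of the triple-exponential basis
#'
#' The unnormalized basis
#' \eqn{f(t) = w e^{-t/T_{c2}} + (1-w) e^{-t/T_{c3}} - e^{-t/T_{c1}}}
#' starts at 0 (coefficients cancel); \code{Fnorm = 1/max_t f(t)} scales
#' its peak to 1. The maximum is located by bounded scalar optimization.
#'
#' @param Tc1,Tc2,Tc3 Time constants (ms); \code{Tc1} is the rise
#'   constant and must be the smallest for a positive waveform.
#' @param w Weighting factor in (0, 1).
#' @return List with \code{Fnorm} and \code{t_peak} (ms).
#' @export
compute_fnorm <- function(Tc1, Tc2, Tc3, w = 0.7384) {
  if (any(c(Tc1, Tc2, Tc3) <= 0)) stop("time constants must be positive")
  if (w <= 0 || w >= 1) stop("w must lie in (0, 1)")
  f <- function(t) w * exp(-t / Tc2) + (1 - w) * exp(-t / Tc3) - exp(-t / Tc1)
  hi <- 10 * max(Tc1, Tc2, Tc3)
  opt <- stats::optimize(f, c(0, hi), maximum = TRUE, tol = 1e-10)
  if (opt$objective <= 0)
    stop("basis waveform has non-positive maximum; invalid time-constant ",
         "triplet (need Tc1 < min(Tc2, Tc3))")
  list(Fnorm = 1 / opt$objective, t_peak = opt$maximum)
}

#' Basis waveform parameters
#'
#' @param Tc1,Tc2,Tc3 Time constants (ms).
#' @param w Weighting factor in (0, 1); default 0.7384 (grid-search value
#'   shared by all orders).
#' @return Object of class \code{basis_params} with the triplet, \code{w},
#'   \code{Fnorm}, and \code{t_peak}.
#' @export
basis_params <- function(Tc1, Tc2, Tc3, w = 0.7384) {
  fn <- compute_fnorm(Tc1, Tc2, Tc3, w)
  structure(list(Tc1 = Tc1, Tc2 = Tc2, Tc3 = Tc3, w = w,
                 Fnorm = fn$Fnorm, t_peak = fn$t_peak),
            class = "basis_params")
}

#' Normalized triple-exponential basis waveform
#'
#' \deqn{O_{norm}(t) = F_{norm} (w e^{-t/T_{c2}} + (1-w) e^{-t/T_{c3}}
#'   - e^{-t/T_{c1}})}
#' Zero at t = 0, unit peak, decaying to zero; zero for t < 0.
#'
#' @param t Time since the event (ms); vectorized.
#' @param params A \code{\link{basis_params}}.
#' @return Normalized open probability in [0, 1].
#' @export
basis_waveform <- function(t, params) {
  stopifnot(inherits(params, "basis_params"))
  out <- numeric(length(t))
  pos <- t >= 0
  tp <- t[pos]
  out[pos] <- params$Fnorm *
    (params$w * exp(-tp / params$Tc2) +
       (1 - params$w) * exp(-tp / params$Tc3) -
       exp(-tp / params$Tc1))
  out
}

#' Order categorization of synaptic events
#'
#' The order of an event is 1 plus the number of earlier events within the
#' memory window \code{M} of that event (sliding look-back), capped at
#' \code{max_order}: after a silent period longer than M the next event is
#' first-order again.
#'
#' @param event_times Sorted event times (ms).
#' @param M Memory window (ms), default 1000.
#' @param max_order Order cap, default 5.
#' @return Integer vector of orders, one per event.
#' @examples
#' categorize_orders(c(0, 500, 1600))             # 1 2 1
#' categorize_orders(seq(0, 500, by = 100))       # 1 2 3 4 5 5
#' @export
categorize_orders <- function(event_times, M = 1000, max_order = 5) {
  if (is.unsorted(event_times)) stop("event_times must be sorted")
  vapply(seq_along(event_times), function(k) {
    n_prior <- sum(event_times[k] - event_times[seq_len(k - 1)] <= M)
    as.integer(min(n_prior + 1L, max_order))
  }, integer(1))
}

# Quantize interpulse intervals to multiples of delta: nearest multiple,
# ties rounded up, minimum delta.
quantize_intervals <- function(gaps, delta) {
  q <- floor(gaps / delta + 0.5) * delta
  pmax(q, delta)
}

lut_key <- function(order, gaps) {
  if (order == 1L) "1|" else paste0(order, "|", paste(gaps, collapse = ","))
}

#' Build a look-up-table surrogate model
#'
#' The table maps (order, quantized interpulse-interval tuple) to the
#' teacher kinetic model's absolute peak open probability following the
#' final pulse of that pattern, simulated with the synaptic glutamate
#' transient at physiological co-agonist conditions. \code{"on_demand"}
#' (default) computes entries lazily with memoization; \code{"exhaustive"}
#' enumerates all admissible tuples up front and refuses configurations
#' above \code{entry_budget} (order-5 enumeration at M = 1000, delta = 5
#' is combinatorially infeasible).
#'
#' @param scheme Teacher \code{kinetic_scheme}.
#' @param basis Optional list of \code{basis_params}, one per order
#'   (from \code{\link{train_basis}}); required before prediction.
#' @param M Memory window (ms).
#' @param delta Interval granularity (ms); must divide M.
#' @param max_order Order cap.
#' @param mode \code{"on_demand"} or \code{"exhaustive"}.
#' @param peak Transient peak concentration (uM).
#' @param tau_clear Transient clearance constant (ms).
#' @param glycine Glycine concentration (uM), default 20 (0.02 mM).
#' @param dt Teacher simulation step (ms).
#' @param peak_window Time after the final pulse searched for the peak (ms).
#' @param entry_budget Maximum table size for exhaustive mode.
#' @return Object of class \code{lut_model}.
#' @export
build_lut <- function(scheme, basis = NULL, M = 1000, delta = 5,
                      max_order = 5, mode = c("on_demand", "exhaustive"),
                      peak = 1100, tau_clear = 1.2, glycine = 20,
                      dt = 0.1, peak_window = 50, entry_budget = 2e6) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  mode <- match.arg(mode)
  if (M %% delta != 0) stop("delta must divide M")
  model <- structure(
    list(M = M, delta = delta, max_order = max_order, mode = mode,
         basis = basis, teacher = scheme,
         transient = list(peak = peak, tau_clear = tau_clear,
                          glycine = glycine),
         dt = dt, peak_window = peak_window,
         table = new.env(parent = emptyenv())),
    class = "lut_model")
  if (mode == "exhaustive") {
    # count admissible tuples in closed form before materializing anything:
    # (k-1) positive multiples of delta summing to <= M <=> choose(M/delta, k-1)
    n_entries <- sum(choose(M / delta, seq_len(max_order) - 1L))
    if (n_entries > entry_budget)
      stop("exhaustive table would hold ", format(n_entries, big.mark = ","),
           " entries (> budget ", entry_budget,
           "); use mode = 'on_demand'")
    tuples <- enumerate_tuples(M, delta, max_order)
    for (tp in tuples)
      model$table[[lut_key(length(tp) + 1L, tp)]] <- teacher_peak(model, tp)
  }
  model
}

# All admissible quantized gap tuples: for order k, k-1 gaps, each a
# positive multiple of delta, spanning at most M in total. Order 1 is the
# empty tuple.
enumerate_tuples <- function(M, delta, max_order) {
  out <- list(numeric(0))
  grow <- list(numeric(0))
  for (k in seq_len(max_order - 1L)) {
    nxt <- list()
    for (tp in grow) {
      room <- M - sum(tp)
      if (room >= delta) {
        for (g in seq(delta, room, by = delta))
          nxt[[length(nxt) + 1L]] <- c(tp, g)
      }
    }
    out <- c(out, nxt)
    grow <- nxt
  }
  out
}

#' Look up (or compute) the amplitude for a quantized pattern
#'
#' @param model A \code{lut_model}.
#' @param order Response order (1..max_order).
#' @param gaps Quantized interpulse intervals (ms), length
#'   \code{order - 1}, chronological.
#' @return Peak open probability of the teacher after the final pulse of
#'   the pattern.
#' @export
lut_amplitude <- function(model, order, gaps = numeric(0)) {
  stopifnot(inherits(model, "lut_model"))
  if (length(gaps) != order - 1L)
    stop("order ", order, " requires ", order - 1L, " intervals")
  key <- lut_key(order, gaps)
  val <- model$table[[key]]
  if (!is.null(val)) return(val)
  if (model$mode == "exhaustive")
    stop("missing table entry '", key, "' in exhaustive mode")
  val <- teacher_peak(model, gaps)
  model$table[[key]] <- val
  val
}

# Simulate the teacher on the reconstructed pattern and return the peak
# open probability after the final pulse.
teacher_peak <- function(model, gaps) {
  ev <- cumsum(c(0, gaps))
  last <- ev[length(ev)]
  stim <- synaptic_transient(ev, peak = model$transient$peak,
                             tau_clear = model$transient$tau_clear,
                             glycine = model$transient$glycine)
  sim <- simulate_scheme(model$teacher, stim, last + model$peak_window,
                         dt = model$dt)
  max(sim$open_probability[sim$time >= last])
}

#' Predict an open-probability trace with the LUTsyn model
#'
#' Each event's interpulse intervals (to the previous order-1 events) are
#' quantized to the table granularity, its amplitude is retrieved from the
#' table, and the order's basis waveform is emitted scaled so the summed
#' output peaks at the stored amplitude. Because stored amplitudes are
#' absolute peaks (residual occupancy included), overlapping waveforms
#' must not double-count the running tail; two combination rules are
#' provided:
#' \describe{
#'   \item{\code{"additive"} (default)}{each event contributes an
#'     increment \code{max(amplitude - tail, 0)} times its basis
#'     waveform, added to the tails of earlier events. This avoids the
#'     transient dip to zero at each event onset (the basis starts at 0
#'     while the receptor carries residual occupancy) and tracks the
#'     teacher markedly better on dense trains.}
#'   \item{\code{"supersede"}}{between consecutive events the output is
#'     the most recent event's scaled waveform alone.}
#' }
#'
#' @param model A \code{lut_model} with trained \code{basis}.
#' @param event_times Sorted event times (ms).
#' @param duration Output duration (ms); default covers the last event
#'   plus the memory window.
#' @param dt Output grid step (ms).
#' @param rule Overlap combination rule (see above).
#' @return List with \code{time}, \code{open_probability},
#'   \code{orders}, \code{amplitudes}.
#' @export
lut_predict <- function(model, event_times, duration = NULL, dt = 0.1,
                        rule = c("additive", "supersede")) {
  stopifnot(inherits(model, "lut_model"))
  rule <- match.arg(rule)
  if (is.null(model$basis))
    stop("model has no basis waveforms; run train_basis() first")
  if (is.unsorted(event_times)) stop("event_times must be sorted")
  if (is.null(duration))
    duration <- if (length(event_times)) max(event_times) + model$M else 1000
  time <- seq(0, duration, by = dt)
  op <- numeric(length(time))
  if (length(event_times) == 0L)
    return(list(time = time, open_probability = op,
                orders = integer(0), amplitudes = numeric(0)))
  orders <- categorize_orders(event_times, model$M, model$max_order)
  amps <- numeric(length(event_times))
  bounds <- c(event_times, Inf)
  for (k in seq_along(event_times)) {
    o <- orders[k]
    gaps <- if (o > 1L)
      quantize_intervals(diff(event_times[(k - o + 1L):k]), model$delta)
    else numeric(0)
    amps[k] <- lut_amplitude(model, o, gaps)
    if (rule == "additive") {
      i0 <- which(time >= event_times[k])[1]
      inc <- max(amps[k] - op[i0], 0)
      op[i0:length(op)] <- op[i0:length(op)] +
        inc * basis_waveform(time[i0:length(op)] - event_times[k],
                             model$basis[[o]])
    } else {
      idx <- which(time >= event_times[k] & time < bounds[k + 1])
      op[idx] <- amps[k] *
        basis_waveform(time[idx] - event_times[k], model$basis[[o]])
    }
  }
  list(time = time, open_probability = pmin(pmax(op, 0), 1),
       orders = orders, amplitudes = amps)
}

#' Mean per-order responses from a teacher trace
#'
#' Extracts, for each event, the trace segment from the event to the next
#' event (or trace end), normalizes each segment to unit peak, groups
#' segments by order, and averages. At each time offset the mean is taken
#' over the segments that extend that far; the mean is cut where fewer
#' than \code{min_instances} segments remain, so the decay phase is
#' represented out to the longest interpulse intervals instead of being
#' truncated to the shortest one.
#'
#' @param time,trace Teacher simulation grid and open-probability series.
#' @param event_times Sorted event times (ms).
#' @param M,max_order Categorization parameters.
#' @param min_instances Minimum segments required per order (and minimum
#'   coverage per retained time offset).
#' @return List indexed by order: \code{time} (relative, ms), \code{mean}
#'   waveform, \code{coverage} (segments per offset), \code{n} instances.
#' @export
mean_order_responses <- function(time, trace, event_times, M = 1000,
                                 max_order = 5, min_instances = 3) {
  dt <- time[2] - time[1]
  segs <- extract_order_segments(time, trace, event_times, M, max_order)
  out <- vector("list", max_order)
  deficient <- integer(0)
  for (o in seq_len(max_order)) {
    grp <- segs[[o]]
    if (length(grp) < min_instances) {
      deficient <- c(deficient, o)
      next
    }
    out[[o]] <- pooled_mean_waveform(grp, dt, min_instances)
  }
  if (length(deficient))
    stop("too few instances (< ", min_instances, ") for order(s) ",
         paste(deficient, collapse = ", "),
         "; regenerate the training train with a new seed")
  out
}

# Unit-normalized per-event segments (event to next event or trace end),
# grouped by response order.
extract_order_segments <- function(time, trace, event_times, M = 1000,
                                   max_order = 5) {
  orders <- categorize_orders(event_times, M, max_order)
  dt <- time[2] - time[1]
  bounds <- c(event_times, max(time) + dt)
  segs <- lapply(seq_along(event_times), function(k) {
    idx <- which(time >= event_times[k] & time < bounds[k + 1])
    y <- trace[idx]
    if (length(y) < 3 || max(y) <= 0) return(NULL)
    y / max(y)
  })
  lapply(seq_len(max_order), function(o) {
    grp <- segs[orders == o]
    grp[!vapply(grp, is.null, logical(1))]
  })
}

# Coverage-based mean of variable-length segments: at each offset the mean
# runs over the segments that extend that far, cut where coverage drops
# below min_instances.
pooled_mean_waveform <- function(grp, dt, min_instances = 3) {
  n_max <- max(lengths(grp))
  mat <- matrix(NA_real_, n_max, length(grp))
  for (j in seq_along(grp)) mat[seq_along(grp[[j]]), j] <- grp[[j]]
  coverage <- rowSums(!is.na(mat))
  keep <- seq_len(max(which(coverage >= min_instances)))
  list(time = (keep - 1) * dt,
       mean = rowMeans(mat[keep, , drop = FALSE], na.rm = TRUE),
       coverage = coverage[keep], n = length(grp))
}

#' Fit a basis-waveform triplet to a target waveform with PSO
#'
#' Minimizes NRMSE between the target and candidate basis waveforms plus
#' the absolute percent error of their full durations at half maximum
#' (the FDHM term is dropped when the target segment is truncated before
#' re-crossing half maximum).
#'
#' @param time Relative time grid of the target waveform (ms).
#' @param waveform Target waveform, unit peak.
#' @param w Fixed weighting factor.
#' @param config A \code{\link{pso_config}}.
#' @param bounds List \code{lower}/\code{upper} for (Tc1, Tc2, Tc3) in ms.
#' @return List with \code{params} (\code{basis_params}), \code{loss},
#'   \code{history}.
#' @export
fit_basis_to_waveform <- function(time, waveform, w = 0.7384,
                                  config = pso_config(50, 200, seed = 1),
                                  bounds = list(lower = c(0.1, 1, 20),
                                                upper = c(30, 400, 1500))) {
  target_fdhm <- tryCatch(fdhm(time, waveform), error = function(e) NULL)
  loss_one <- function(Tc1, Tc2, Tc3) {
    bp <- tryCatch(basis_params(Tc1, Tc2, Tc3, w), error = function(e) NULL)
    if (is.null(bp)) return(Inf)
    est <- basis_waveform(time, bp)
    loss <- nrmse(waveform, est)
    if (!is.null(target_fdhm)) {
      tg <- seq(0, 12 * max(Tc2, Tc3), length.out = 4000)
      cand_fdhm <- tryCatch(fdhm(tg, basis_waveform(tg, bp)),
                            error = function(e) NULL)
      if (is.null(cand_fdhm)) return(Inf)
      loss <- loss + abs(cand_fdhm - target_fdhm) / target_fdhm
    }
    loss
  }
  # w != 0.5 breaks the (Tc2, w) <-> (Tc3, 1-w) label symmetry, which
  # otherwise leaves a spurious role-swapped local minimum; evaluate both
  # assignments and keep the better one.
  obj <- function(p) min(loss_one(p[1], p[2], p[3]),
                         loss_one(p[1], p[3], p[2]))
  # moment-matched warm starts: the rise constant tracks the peak time and
  # the decay constants the width at half maximum
  t_peak <- time[which.max(waveform)]
  warm <- if (!is.null(target_fdhm)) {
    rbind(c(t_peak / 3, target_fdhm / log(2), 3 * target_fdhm / log(2)),
          c(t_peak / 3, target_fdhm / 2, 1.5 * target_fdhm),
          c(t_peak / 2, target_fdhm, 4 * target_fdhm),
          c(t_peak / 3, target_fdhm / 2, 8 * target_fdhm),
          c(t_peak / 2, target_fdhm / 3, 15 * target_fdhm))
  } else NULL
  res <- pso_optimize(obj, bounds$lower, bounds$upper, config,
                      init_points = warm)
  p <- res$par
  if (loss_one(p[1], p[3], p[2]) < loss_one(p[1], p[2], p[3]))
    p <- p[c(1, 3, 2)]
  list(params = basis_params(p[1], p[2], p[3], w),
       loss = res$value, history = res$history)
}

#' Train per-order basis waveforms from the teacher model
#'
#' Simulates the teacher on a Poisson event train, categorizes every
#' response by order, averages the normalized per-order segments, and
#' fits a triple-exponential basis to each mean response with PSO
#' (NRMSE + FDHM percent-error loss, w fixed).
#'
#' @param scheme Teacher \code{kinetic_scheme}.
#' @param train_events Event times (ms) of the training train; default a
#'   4 Hz Poisson train of 40 s drawn with \code{train_seed}.
#' @param train_seed Seed for the default training train(s).
#' @param w Weighting factor (fixed).
#' @param config PSO configuration per order (default 50 particles, 200
#'   generations).
#' @param M,max_order Categorization parameters.
#' @param peak,tau_clear,glycine Synaptic transient parameters (uM, ms, uM).
#' @param dt Teacher simulation step (ms).
#' @param min_support Minimum duration (ms) each order's mean response
#'   must cover so its decay phase is identifiable; further trains (seeds
#'   \code{train_seed + 1, ...}) are drawn and pooled while any order
#'   falls short. Rare orders (a 4 Hz train contains only a handful of
#'   first-order events per 40 s) would otherwise truncate the mean
#'   before the slow decay component is visible.
#' @param max_trains Cap on pooled training trains.
#' @return List with \code{basis} (per-order \code{basis_params}),
#'   \code{fits}, \code{mean_responses}, \code{train_events}.
#' @export
train_basis <- function(scheme, train_events = NULL, train_seed = 1,
                        w = 0.7384, config = pso_config(50, 200, seed = 1),
                        M = 1000, max_order = 5,
                        peak = 1100, tau_clear = 1.2, glycine = 20,
                        dt = 0.1, min_support = 400, max_trains = 5) {
  simulate_train <- function(ev) {
    stim <- synaptic_transient(ev, peak = peak, tau_clear = tau_clear,
                               glycine = glycine)
    sim <- simulate_scheme(scheme, stim, max(ev) + M, dt = dt)
    extract_order_segments(sim$time, sim$open_probability, ev, M, max_order)
  }

  if (!is.null(train_events)) {
    all_events <- list(train_events)
    segs <- simulate_train(train_events)
  } else {
    all_events <- list()
    segs <- rep(list(list()), max_order)
    for (j in seq_len(max_trains)) {
      ev <- poisson_train(4, 40000, seed = train_seed + j - 1L,
                          min_spacing = 5)
      all_events[[j]] <- ev
      new_segs <- simulate_train(ev)
      segs <- lapply(seq_len(max_order),
                     function(o) c(segs[[o]], new_segs[[o]]))
      support <- vapply(segs, function(grp) {
        if (length(grp) < 3) return(0)
        pm <- pooled_mean_waveform(grp, dt)
        max(pm$time)
      }, numeric(1))
      if (all(support >= min_support)) break
    }
  }

  deficient <- which(lengths(segs) < 3L)
  if (length(deficient))
    stop("too few instances for order(s) ",
         paste(deficient, collapse = ", "),
         "; provide a longer training train or another seed")
  mr <- lapply(segs, pooled_mean_waveform, dt = dt)
  fits <- lapply(seq_len(max_order), function(o) {
    fit_basis_to_waveform(mr[[o]]$time, mr[[o]]$mean, w = w, config = config)
  })
  list(basis = lapply(fits, `[[`, "params"),
       fits = fits, mean_responses = mr, train_events = all_events)
}

#' Validate a LUT model against its teacher
#'
#' @param model A \code{lut_model} with basis waveforms.
#' @param event_times Held-out validation event train (ms).
#' @param duration Validation duration (ms); default last event + 500.
#' @param dt Comparison grid (ms).
#' @return List with \code{nrmse}, \code{teacher}, \code{prediction}.
#' @export
validate_lut <- function(model, event_times, duration = NULL, dt = 0.1) {
  if (is.null(duration)) duration <- max(event_times) + 500
  stim <- synaptic_transient(event_times, peak = model$transient$peak,
                             tau_clear = model$transient$tau_clear,
                             glycine = model$transient$glycine)
  teach <- simulate_scheme(model$teacher, stim, duration, dt = dt)
  pred <- lut_predict(model, event_times, duration, dt = dt)
  list(nrmse = nrmse(teach$open_probability, pred$open_probability),
       teacher = teach, prediction = pred)
}

#' Serialize / restore a LUT model as JSON
#'
#' Stores metadata (M, delta, w, per-order time-constant triplets and
#' Fnorm, transient parameters, teacher rate constants) and every
#' memoized table entry; the round trip is exact.
#'
#' @param model A \code{lut_model}.
#' @param path JSON file path.
#' @return \code{read_lut} returns a \code{lut_model}.
#' @export
write_lut <- function(model, path) {
  stopifnot(inherits(model, "lut_model"))
  entries <- as.list(model$table)
  payload <- list(
    M = model$M, delta = model$delta, max_order = model$max_order,
    mode = model$mode, dt = model$dt, peak_window = model$peak_window,
    transient = model$transient,
    teacher_rates = as.list(unclass(model$teacher$rates)),
    teacher_factors = model$teacher$statistical_factors,
    basis = if (is.null(model$basis)) NULL else
      lapply(model$basis, function(b)
        list(Tc1 = b$Tc1, Tc2 = b$Tc2, Tc3 = b$Tc3, w = b$w)),
    table = entries)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lut
#' @export
read_lut <- function(path) {
  p <- jsonlite::read_json(path)
  scheme <- build_scheme(rate_constants(p$teacher_rates), p$teacher_factors)
  basis <- if (is.null(p$basis) || length(p$basis) == 0) NULL else
    lapply(p$basis, function(b) basis_params(b$Tc1, b$Tc2, b$Tc3, b$w))
  model <- build_lut(scheme, basis = basis, M = as.numeric(p$M),
                     delta = as.numeric(p$delta),
                     max_order = as.integer(p$max_order), mode = "on_demand",
                     peak = as.numeric(p$transient$peak),
                     tau_clear = as.numeric(p$transient$tau_clear),
                     glycine = as.numeric(p$transient$glycine),
                     dt = as.numeric(p$dt),
                     peak_window = as.numeric(p$peak_window))
  model$mode <- p$mode
  for (k in names(p$table)) model$table[[k]] <- as.numeric(p$table[[k]])
  model
}

#' @export
print.lut_model <- function(x, ...) {
  cat("LUTsyn model: M =", x$M, "ms, delta =", x$delta,
      "ms, max order", x$max_order, "|", x$mode, "mode\n")
  cat("memoized entries:", length(ls(x$table)),
      "| basis:", if (is.null(x$basis)) "untrained" else "trained", "\n")
  invisible(x)
}
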