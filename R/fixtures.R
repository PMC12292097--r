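# Synthetic fixtures: analytic waveforms with machine-precision ground
# truth, written as CSV plus a JSON manifest. Everything regenerates
# deterministically from its parameters.

#' Generate analytic exponential waveforms with known ground truth
#'
#' Builds mono-, bi-, or triple-exponential (basis-shaped) waveforms on a
#' uniform grid and records closed-form ground truth (time constants,
#' weighted tau, FDHM where available) in a manifest.
#'
#' @param spec A list of waveform descriptions; each element is a list
#'   with \code{name}, \code{type} (\code{"mono"}, \code{"bi"},
#'   \code{"tri"}), and parameters: mono: \code{tau}; bi: \code{A1},
#'   \code{A2}, \code{tau1}, \code{tau2}; tri: \code{Tc1}, \code{Tc2},
#'   \code{Tc3}, \code{w}.
#' @param dir Output directory (created if needed); \code{NULL} returns
#'   waveforms without writing files.
#' @param duration,dt Grid (ms).
#' @return Invisibly, a list per waveform: \code{time}, \code{values},
#'   \code{truth}; with \code{dir} set, files \code{<name>.csv} and
#'   \code{manifest.json} are written.
#' @export
make_analytic_waveforms <- function(spec, dir = NULL, duration = 1000,
                                    dt = 0.1) {
  time <- seq(0, duration, by = dt)
  out <- lapply(spec, function(s) {
    v <- switch(s$type,
      mono = {
        truth <- list(tau = s$tau, fdhm = s$tau * log(2),
                      weighted_tau = s$tau)
        list(values = exp(-time / s$tau), truth = truth)
      },
      bi = {
        wt <- (s$A1 * s$tau1 + s$A2 * s$tau2) / (s$A1 + s$A2)
        truth <- list(tau1 = s$tau1, tau2 = s$tau2, A1 = s$A1, A2 = s$A2,
                      weighted_tau = wt)
        list(values = s$A1 * exp(-time / s$tau1) +
               s$A2 * exp(-time / s$tau2), truth = truth)
      },
      tri = {
        bp <- basis_params(s$Tc1, s$Tc2, s$Tc3,
                           if (is.null(s$w)) 0.7384 else s$w)
        truth <- list(Tc1 = s$Tc1, Tc2 = s$Tc2, Tc3 = s$Tc3, w = bp$w,
                      Fnorm = bp$Fnorm, t_peak = bp$t_peak, peak = 1)
        list(values = basis_waveform(time, bp), truth = truth)
      },
      stop("unknown waveform type '", s$type, "'"))
    list(name = s$name, time = time, values = v$values, truth = v$truth)
  })
  names(out) <- vapply(spec, `[[`, character(1), "name")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (w in out)
      utils::write.csv(data.frame(time_ms = w$time, value = w$values),
                       file.path(dir, paste0(w$name, ".csv")),
                       row.names = FALSE)
    manifest <- lapply(out, function(w)
      c(w$truth, list(duration = duration, dt = dt)))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}
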