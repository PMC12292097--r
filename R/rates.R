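#' Names of the twelve rate constants of the nine-state kinetic scheme
#'
#' Order is fixed and used everywhere a rate-constant set is treated as a
#' plain numeric vector (optimization, JSON round-trips).
#'
#' @format Character vector of length 12.
#' @export
RATE_NAMES <- c("kon", "koff", "k32", "k23", "k21", "k12",
                "k1_O1", "kO1_1", "kO1_O2", "kO2_O1",
                "kgly_on", "kgly_off")

# Built-in presets: pre- and post-optimization values of the twelve rate
# constants. Association constants (kon, kgly_on) are in uM^-1 s^-1, all
# others in s^-1.
.RATE_PRESETS <- list(
  original = c(kon = 17, koff = 60, k32 = 127, k23 = 161, k21 = 580,
               k12 = 2610, k1_O1 = 2508, kO1_1 = 2167, kO1_O2 = 3449,
               kO2_O1 = 662, kgly_on = 5, kgly_off = 12),
  optimized = c(kon = 46, koff = 86, k32 = 208, k23 = 152, k21 = 1200,
                k12 = 5000, k1_O1 = 1130, kO1_1 = 4823, kO1_O2 = 6998,
                kO2_O1 = 278, kgly_on = 1, kgly_off = 24)
)

#' Construct a validated set of rate constants
#'
#' The nine-state scheme has twelve rate constants: glutamate association
#' and dissociation (\code{kon}, \code{koff}), the diliganded closed-state
#' transitions (\code{k32}, \code{k23}, \code{k21}, \code{k12}), the gating
#' steps C1--O1 and O1--O2 (\code{k1_O1}, \code{kO1_1}, \code{kO1_O2},
#' \code{kO2_O1}), and glycine association/dissociation (\code{kgly_on},
#' \code{kgly_off}). Association constants are in uM^-1 s^-1; all other
#' rates in s^-1.
#'
#' @param x Named numeric vector or list with exactly the twelve keys in
#'   \code{\link{RATE_NAMES}}, or a preset name \code{"original"} /
#'   \code{"optimized"}.
#' @return A named numeric vector of class \code{rate_constants}.
#' @examples
#' rate_constants("optimized")["kon"]  # 46 uM^-1 s^-1
#' @export
rate_constants <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!x %in% names(.RATE_PRESETS))
      stop("unknown rate preset '", x, "'; available: ",
           paste(names(.RATE_PRESETS), collapse = ", "))
    x <- .RATE_PRESETS[[x]]
  }
  if (inherits(x, "rate_constants")) return(x)
  x <- unlist(x)
  if (is.null(names(x)) || !setequal(names(x), RATE_NAMES) ||
      length(x) != 12L)
    stop("rate constants must be a named vector with exactly the keys: ",
         paste(RATE_NAMES, collapse = ", "))
  x <- x[RATE_NAMES]
  bad <- !is.finite(x) | x <= 0
  if (any(bad))
    stop("rate constants must be strictly positive and finite; offending: ",
         paste(RATE_NAMES[bad], collapse = ", "))
  structure(x, class = "rate_constants")
}

#' Read or write rate constants as flat JSON
#'
#' The on-disk format is a flat JSON object with exactly the twelve keys of
#' \code{\link{RATE_NAMES}}.
#'
#' @param path File path.
#' @param rates A \code{rate_constants} object (for writing).
#' @return \code{read_rate_constants} returns a \code{rate_constants}
#'   object; \code{write_rate_constants} returns \code{path} invisibly.
#' @export
read_rate_constants <- function(path) {
  rate_constants(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_rate_constants
#' @export
write_rate_constants <- function(rates, path) {
  rates <- rate_constants(rates)
  jsonlite::write_json(as.list(unclass(rates)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("NMDA-R kinetic rate constants (kon, kgly_on in uM^-1 s^-1; rest s^-1)\n")
  print(unclass(x), ...)
  invisible(x)
}
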