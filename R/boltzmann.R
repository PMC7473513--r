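#' Boltzmann growth sigmoid
#'
#' The Boltzmann growth equation
#' \deqn{I(t) = A_1 + \frac{A_2 - A_1}{1 + e^{-(t - t_0)/dx}}}
#' is the kinetic model used throughout this package for both the assembly
#' (rising) and, mirrored in time, the disassembly (falling) phase of ESCRT
#' recruitment at a budding site. `A1` and `A2` are the lower and upper
#' asymptotes in arbitrary fluorescence units (a.u.), `t0` is the midpoint
#' (where \eqn{I = (A_1 + A_2)/2}) and `dx` sets the steepness: the maximum
#' slope is \eqn{(A_2 - A_1)/(4\,dx)} and the 10\%-to-90\% rise time is
#' \eqn{\ln(81)\,dx}.
#'
#' @param t numeric vector of times (s).
#' @param A1 lower asymptote (a.u.).
#' @param A2 upper asymptote (a.u.).
#' @param t0 midpoint time (s).
#' @param dx width parameter (s); must be non-zero. Use
#'   `direction = "falling"` rather than a negative `dx` for decay.
#' @param direction `"rising"` (default) or `"falling"`; falling mirrors
#'   the sigmoid in time about `t0` so that `A2` is approached as
#'   \eqn{t \to -\infty}.
#' @return numeric vector of intensities, same length as `t`.
#' @examples
#' boltzmann_curve(0, A1 = 0, A2 = 10000, t0 = 0, dx = 25)   # 5000
#' boltzmann_rate(A1 = 0, A2 = 10000, dx = 25)               # 100 a.u./s
#' @export
boltzmann_curve <- function(t, A1, A2, t0, dx,
                            direction = c("rising", "falling")) {
  direction <- match.arg(direction)
  if (!is.numeric(dx) || length(dx) != 1L || !is.finite(dx) || dx == 0) {
    stop_invalid("'dx' must be a single non-zero finite number")
  }
  s <- if (direction == "rising") 1 else -1
  A1 + (A2 - A1) / (1 + exp(-s * (t - t0) / dx))
}

#' @describeIn boltzmann_curve maximum slope \eqn{(A_2 - A_1)/(4\,dx)} of
#'   the sigmoid, the single-number rate used for assembly/disassembly
#'   rates (a.u./s).
#' @export
boltzmann_rate <- function(A1, A2, dx) {
  if (any(dx == 0)) stop_invalid("'dx' must be non-zero")
  abs(A2 - A1) / (4 * abs(dx))
}
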