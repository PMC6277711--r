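#' Patent value under exponential depreciation
#'
#' The value of a drug patent decays at a rate proportional to its current
#' level, `dV/dt = -V / (tau + 1/d)`, where `tau` is the patent technology
#' life cycle and `d` the substitutability of patent technologies. The
#' closed-form solution `V(t) = v0 * exp(-t / (tau + 1/d))` is used at step
#' boundaries; the autonomous linear ODE makes Euler stepping unnecessary
#' (it is retained in the test suite as an independent oracle).
#'
#' @param v0 Initial patent value (= initial R&D investment), dollars.
#' @param tau Patent technology life cycle, years (> 0).
#' @param d Substitutability of patent technologies (> 0).
#' @param t Time since launch, years (>= 0); may be a vector.
#' @return Patent value at `t`, same length as `t`.
#' @examples
#' patent_value(5e7, tau = 10, d = 0.05, t = 30) / 5e7 # exp(-1)
#' @export
patent_value <- function(v0, tau, d, t) {
  if (!is.numeric(tau) || tau <= 0) stop("tau: must be > 0")
  if (!is.numeric(d) || d <= 0) stop("d: must be > 0")
  if (any(t < 0)) stop("t: must be >= 0")
  if (v0 < 0) stop("v0: must be >= 0")
  v0 * exp(-t / (tau + 1 / d))
}

#' Relative patent intensity
#'
#' The relative patent intensity of the in-pool originator is its current
#' patent value divided by the total over competing enterprises,
#' `r = v_in / (v_in + v_out)`. Because all patents depreciate with the same
#' time constant, `r` is constant along a trajectory and scale-invariant.
#'
#' @param v_in Current patent value of the in-pool originator (>= 0).
#' @param v_out Current patent value of the out-of-pool competitor
#'   aggregate (>= 0).
#' @return A fraction in [0, 1].
#' @export
relative_intensity <- function(v_in, v_out) {
  if (any(v_in < 0) || any(v_out < 0)) stop("patent values must be >= 0")
  tot <- v_in + v_out
  if (any(tot <= 0)) {
    stop("degenerate patent state: v_in + v_out must be > 0")
  }
  v_in / tot
}

#' Pooling subsidy
#'
#' The one-time government subsidy paid to the originator at pool entry: the
#' product of the pooling subsidy coefficient and the originator's initial
#' R&D investment in the current market.
#'
#' @param subsidy_coef Pooling subsidy coefficient (>= 0).
#' @param v0_market Initial market-level R&D investment, dollars (>= 0).
#' @return Subsidy amount, dollars.
#' @examples
#' pooling_subsidy(0.05, 5e7) # $2.5e6
#' @export
pooling_subsidy <- function(subsidy_coef, v0_market) {
  if (subsidy_coef < 0) stop("subsidy_coef: must be >= 0")
  if (v0_market < 0) stop("v0_market: must be >= 0")
  subsidy_coef * v0_market
}
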