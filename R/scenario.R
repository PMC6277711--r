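#' Scenario: one simulated world
#'
#' A scenario describes a single world to simulate: whether the originator
#' and government join the Medicines Patent Pool, the policy levers (generic
#' price ratio, royalty rate, pooling subsidy coefficient), and the event
#' timing (launch, pool entry, patent life, generic development lag, horizon
#' and step length).
#'
#' @param pooled Logical; does the originator (with the government) join the
#'   MPP in this world?
#' @param price_ratio Generic price / original price, in (0, 1]. Default 0.4,
#'   the studied drug's post-negotiation ratio.
#' @param royalty_rate Royalty paid by the licensed generic maker, as a
#'   fraction of its sales revenue, in [0, 1). Applies only in pooled worlds.
#' @param subsidy_coef Pooling subsidy coefficient; the one-time government
#'   subsidy at pool entry is `subsidy_coef * v0_in`.
#' @param t_launch Launch time of the original drug, years (0 by convention).
#' @param t_join MPP entry time, years (pooled worlds).
#' @param patent_life Years from launch to patent expiry (default 12).
#' @param generic_lag Generic development lag, years (default 2): the
#'   licensed generic launches at `t_join + generic_lag` in pooled worlds and
#'   at `patent_life + generic_lag` otherwise.
#' @param horizon Simulated span, years (default 16).
#' @param dt Step length, years (default 1/6, i.e. 2 months).
#' @return An object of class `mpp_scenario`.
#' @examples
#' default_scenario(pooled = TRUE)
#' @export
mpp_scenario <- function(pooled,
                         price_ratio = 0.4,
                         royalty_rate = 0.1234623,
                         subsidy_coef = 0.065,
                         t_launch = 0,
                         t_join = 0,
                         patent_life = 12,
                         generic_lag = 2,
                         horizon = 16,
                         dt = 1 / 6) {
  s <- list(
    pooled = pooled, price_ratio = price_ratio, royalty_rate = royalty_rate,
    subsidy_coef = subsidy_coef, t_launch = t_launch, t_join = t_join,
    patent_life = patent_life, generic_lag = generic_lag,
    horizon = horizon, dt = dt
  )
  class(s) <- "mpp_scenario"
  validate_scenario(s)
  s
}

#' Default scenario for a pooled or unpooled world
#'
#' 16-year horizon at a 2-month step, 12-year patent life, 2-year generic
#' development lag; pooled worlds join the pool at launch (`t_join = 0`), so
#' the licensed generic enters at year 2 while the out-of-pool generic enters
#' at year 14 (patent expiry + lag).
#'
#' @param pooled Logical.
#' @param ... Overrides passed to [mpp_scenario()].
#' @return An `mpp_scenario` object.
#' @export
default_scenario <- function(pooled, ...) {
  mpp_scenario(pooled = pooled, ...)
}

#' @rdname validate_params
#' @param s An `mpp_scenario` object.
#' @export
validate_scenario <- function(s) {
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)

  if (!is.logical(s$pooled) || length(s$pooled) != 1L || is.na(s$pooled)) {
    note("pooled: must be TRUE or FALSE")
  }
  num1 <- function(f) {
    v <- s[[f]]
    ok <- is.numeric(v) && length(v) == 1L && is.finite(v)
    if (!ok) note(sprintf("%s: must be a finite number", f))
    ok
  }
  if (num1("price_ratio") && (s$price_ratio <= 0 || s$price_ratio > 1)) {
    note(sprintf("price_ratio: must lie in (0, 1], got %g", s$price_ratio))
  }
  if (num1("royalty_rate") && (s$royalty_rate < 0 || s$royalty_rate >= 1)) {
    note(sprintf("royalty_rate: must lie in [0, 1), got %g", s$royalty_rate))
  }
  if (num1("subsidy_coef") && s$subsidy_coef < 0) {
    note("subsidy_coef: must be >= 0")
  }
  ok_t <- num1("t_join") && num1("patent_life") && num1("horizon") &&
    num1("dt") && num1("generic_lag") && num1("t_launch")
  if (ok_t) {
    if (s$t_join < 0 || s$t_join >= s$patent_life) {
      note(sprintf("t_join: must satisfy 0 <= t_join < patent_life (%g), got %g",
                   s$patent_life, s$t_join))
    }
    if (s$patent_life > s$horizon) {
      note(sprintf("patent_life: must be <= horizon (%g), got %g",
                   s$horizon, s$patent_life))
    }
    if (s$dt <= 0) note("dt: must be > 0")
    if (s$generic_lag < 0) note("generic_lag: must be >= 0")
    if (s$dt > 0) {
      n <- s$horizon / s$dt
      if (abs(n - round(n)) > 1e-8) {
        note(sprintf("dt: must divide horizon evenly, got %g / %g = %g",
                     s$horizon, s$dt, n))
      }
    }
  }
  if (length(problems)) {
    stop(structure(
      class = c("mpp_validation_error", "error", "condition"),
      list(
        message = paste0(
          "invalid scenario:\n  ",
          paste(problems, collapse = "\n  ")
        ),
        call = sys.call(-1)
      )
    ))
  }
  invisible(s)
}

#' @export
print.mpp_scenario <- function(x, ...) {
  cat(sprintf("MPP scenario: %s world\n", if (x$pooled) "pooled" else "unpooled"))
  cat(sprintf("  levers: price ratio %.3g, royalty %.3g, subsidy coef %.3g\n",
              x$price_ratio, x$royalty_rate, x$subsidy_coef))
  gen <- if (x$pooled) x$t_join + x$generic_lag else x$patent_life + x$generic_lag
  cat(sprintf("  timing: launch %g y, join %s, generic entry %g y, patent expiry %g y\n",
              x$t_launch, if (x$pooled) sprintf("%g y", x$t_join) else "never", gen,
              x$patent_life))
  cat(sprintf("  horizon %g y at dt %.4g y (%d steps)\n",
              x$horizon, x$dt, as.integer(round(x$horizon / x$dt))))
  invisible(x)
}
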