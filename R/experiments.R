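#' Locate the first sign change of a function tabulated on a grid
#'
#' Scans `f` over a strictly increasing grid and returns the lever value of
#' the first sign change, located by linear interpolation between the
#' bracketing grid points. Exact zeros at grid points are returned as-is.
#'
#' @param grid Strictly increasing numeric vector.
#' @param f Function values on `grid`, same length.
#' @return The interpolated crossing, or `NA_real_` if `f` has no sign
#'   change.
#' @examples
#' g <- seq(0.1, 0.6, by = 0.002)
#' find_crossing(g, g - 0.358)
#' @export
find_crossing <- function(grid, f) {
  if (length(grid) != length(f)) stop("grid and f must have the same length")
  if (length(grid) < 2L) stop("grid must have at least two points")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (any(!is.finite(f))) stop("f must be finite")
  s <- sign(f)
  iz <- which(s == 0)
  ic <- which(s[-length(s)] * s[-1L] < 0)
  first_zero <- if (length(iz)) iz[1L] else Inf
  first_cross <- if (length(ic)) ic[1L] else Inf
  if (is.infinite(first_zero) && is.infinite(first_cross)) return(NA_real_)
  if (first_zero <= first_cross) return(grid[first_zero])
  i <- first_cross
  grid[i] + (grid[i + 1L] - grid[i]) * (0 - f[i]) / (f[i + 1L] - f[i])
}

.sweep_result <- function(lever, grid, table, thresholds) {
  res <- list(lever = lever, grid = grid, table = table,
              thresholds = thresholds)
  class(res) <- "mpp_sweep"
  res
}

.metric_row <- function(value, m) {
  data.frame(
    value = value,
    required_subsidy = m$required_subsidy,
    affordable_subsidy = m$affordable_subsidy,
    d_profit_orig = m$d_profit_orig,
    d_profit_gen = m$d_profit_gen,
    d_gov = m$d_gov,
    joins_orig = m$joins_orig,
    joins_gov = m$joins_gov
  )
}

#' Sweep the generic price ratio
#'
#' For each price ratio, paired pooled/unpooled worlds are run and the
#' pre-subsidy required subsidy (originator cumulative profit shortfall from
#' joining) and affordable subsidy (government cumulative expenditure
#' savings) are computed. The detected threshold is the ratio at which
#' `affordable - required` changes sign: below it the government can
#' compensate the originator's loss and still spend less than out of pool.
#'
#' @param params An `mpp_params` object.
#' @param grid Price-ratio grid in (0, 1], strictly increasing. Default
#'   0.10 to 0.60 in steps of 0.002.
#' @param royalty_rate,subsidy_coef Held fixed across the sweep.
#' @param ... Further scenario fields shared by both worlds.
#' @return An `mpp_sweep` with threshold `price_ratio_crossing`.
#' @export
sweep_price_ratio <- function(params,
                              grid = seq(0.10, 0.60, by = 0.002),
                              royalty_rate = 0.1234623,
                              subsidy_coef = 0.065,
                              ...) {
  if (any(grid <= 0 | grid > 1)) stop("price-ratio grid must lie in (0, 1]")
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    cw <- compare_worlds(params, price_ratio = grid[i],
                         royalty_rate = royalty_rate,
                         subsidy_coef = subsidy_coef, ...)
    rows[[i]] <- .metric_row(grid[i], cw$metrics)
  }
  tab <- do.call(rbind, rows)
  crossing <- find_crossing(grid, tab$affordable_subsidy - tab$required_subsidy)
  .sweep_result("price_ratio", grid, tab,
                list(price_ratio_crossing = crossing))
}

#' Feasible pooling-subsidy-coefficient interval
#'
#' Scans the subsidy coefficient at fixed price ratio and royalty rate and
#' returns the contiguous interval over which both the originator's profit
#' difference and the government's expenditure savings are non-negative
#' (both parties prefer joining). The patient and pre-subsidy economic
#' trajectories do not depend on the coefficient, so the paired worlds are
#' simulated once and the join predicates evaluated at every grid point.
#'
#' @param params An `mpp_params` object.
#' @param price_ratio,royalty_rate Fixed levers.
#' @param s_grid Non-negative, strictly increasing coefficient grid.
#'   Default 0 to 0.20 in steps of 0.001.
#' @param ... Further scenario fields.
#' @return An `mpp_interval`: list with `price_ratio`, `royalty_rate`,
#'   `s_lo`, `s_hi` (NA when empty), `empty`, and the per-point predicate
#'   table.
#' @export
feasible_subsidy_interval <- function(params,
                                      price_ratio,
                                      royalty_rate,
                                      s_grid = seq(0, 0.20, by = 0.001),
                                      ...) {
  if (any(s_grid < 0) || any(diff(s_grid) <= 0)) {
    stop("s_grid must be non-negative and strictly increasing")
  }
  cw <- compare_worlds(params, price_ratio = price_ratio,
                       royalty_rate = royalty_rate,
                       subsidy_coef = s_grid[1L], ...)
  joins_orig <- logical(length(s_grid))
  joins_gov <- logical(length(s_grid))
  for (i in seq_along(s_grid)) {
    m <- decision_metrics(cw$pooled, cw$unpooled, s_grid[i],
                          attr(cw$pooled, "params"))
    joins_orig[i] <- m$joins_orig
    joins_gov[i] <- m$joins_gov
  }
  both <- joins_orig & joins_gov
  idx <- which(both)
  if (length(idx) && any(diff(idx) != 1L)) {
    stop(paste0(
      "feasible subsidy set is non-contiguous on the grid ",
      "(non-monotone configuration); feasible indices: ",
      paste(idx, collapse = ", ")
    ))
  }
  res <- list(
    price_ratio = price_ratio,
    royalty_rate = royalty_rate,
    s_lo = if (length(idx)) s_grid[idx[1L]] else NA_real_,
    s_hi = if (length(idx)) s_grid[idx[length(idx)]] else NA_real_,
    empty = !length(idx),
    required_subsidy = cw$metrics$required_subsidy,
    affordable_subsidy = cw$metrics$affordable_subsidy,
    table = data.frame(subsidy_coef = s_grid, joins_orig = joins_orig,
                       joins_gov = joins_gov, feasible = both)
  )
  class(res) <- "mpp_interval"
  res
}

#' Sweep the royalty rate
#'
#' For each royalty rate, paired worlds are run with all other levers fixed.
#' The detected threshold is the rate above which the generic maker's
#' cumulative in-pool profit falls below its out-of-pool (post-expiry entry)
#' baseline. Government expenditure is structurally independent of the
#' royalty rate.
#'
#' @param params An `mpp_params` object.
#' @param grid Royalty grid in [0, 1), strictly increasing. Default 0 to
#'   0.60 in steps of 0.002.
#' @param price_ratio,subsidy_coef Held fixed across the sweep.
#' @param ... Further scenario fields.
#' @return An `mpp_sweep` with threshold `royalty_rate_ceiling`.
#' @export
sweep_royalty <- function(params,
                          grid = seq(0, 0.60, by = 0.002),
                          price_ratio = 0.4,
                          subsidy_coef = 0.065,
                          ...) {
  if (any(grid < 0 | grid >= 1)) stop("royalty grid must lie in [0, 1)")
  rows <- vector("list", length(grid))
  gov <- numeric(length(grid))
  for (i in seq_along(grid)) {
    cw <- compare_worlds(params, price_ratio = price_ratio,
                         royalty_rate = grid[i],
                         subsidy_coef = subsidy_coef, ...)
    rows[[i]] <- .metric_row(grid[i], cw$metrics)
    gov[i] <- trajectory_totals(cw$pooled)$gov_expenditure_pre_subsidy
  }
  tab <- do.call(rbind, rows)
  tab$gov_expenditure_pooled <- gov
  ceiling <- find_crossing(grid, tab$d_profit_gen)
  .sweep_result("royalty_rate", grid, tab,
                list(royalty_rate_ceiling = ceiling))
}

#' Sweep the R&D investment scale
#'
#' Scales the total initial R&D investment `v0_in + v0_out` over a grid
#' while holding the in/out ratio (hence the relative intensity and all
#' patient dynamics) fixed. The pre-subsidy profit shortfall is invariant to
#' the scale; the decision-relevant difference including the subsidy
#' (proportional to `v0_in`) declines with scale, as does the required
#' subsidy *coefficient* (shortfall / `v0_in`): larger enterprises need a
#' smaller coefficient to be compensated.
#'
#' @param params An `mpp_params` object (its `v0_in`, `v0_out` are
#'   overridden).
#' @param total_v0_grid Strictly increasing grid of total initial R&D
#'   investment, dollars.
#' @param ratio_in_out `v0_in / v0_out`, held fixed (default from `params`).
#' @param price_ratio,royalty_rate,subsidy_coef Fixed levers.
#' @param ... Further scenario fields.
#' @return An `mpp_sweep`; the table adds `required_subsidy_coef`.
#' @export
sweep_rd_scale <- function(params,
                           total_v0_grid = seq(2e7, 2e8, by = 2e7),
                           ratio_in_out = params$v0_in / params$v0_out,
                           price_ratio = 0.4,
                           royalty_rate = 0.1234623,
                           subsidy_coef = 0.065,
                           ...) {
  if (any(diff(total_v0_grid) <= 0) || any(total_v0_grid <= 0)) {
    stop("total_v0_grid must be positive and strictly increasing")
  }
  rows <- vector("list", length(total_v0_grid))
  for (i in seq_along(total_v0_grid)) {
    tot <- total_v0_grid[i]
    p2 <- params
    p2$v0_in <- tot * ratio_in_out / (1 + ratio_in_out)
    p2$v0_out <- tot / (1 + ratio_in_out)
    cw <- compare_worlds(p2, price_ratio = price_ratio,
                         royalty_rate = royalty_rate,
                         subsidy_coef = subsidy_coef, ...)
    row <- .metric_row(tot, cw$metrics)
    row$required_subsidy_coef <- cw$metrics$required_subsidy / p2$v0_in
    rows[[i]] <- row
  }
  .sweep_result("rd_scale", total_v0_grid, do.call(rbind, rows), list())
}

#' Sweep the initial relative patent intensity
#'
#' Varies `v0_in` with `v0_in + v0_out` held fixed, so the initial relative
#' intensity `r0` spans the grid. Lower intensity weakens drug attraction,
#' shrinks the market in both worlds, and lowers the originator's profit
#' difference from joining, making entry likelier.
#'
#' @param params An `mpp_params` object (its `v0_in`, `v0_out` set the
#'   fixed total).
#' @param r0_grid Strictly increasing grid in (0, 1).
#' @param price_ratio,royalty_rate,subsidy_coef Fixed levers.
#' @param ... Further scenario fields.
#' @return An `mpp_sweep`.
#' @export
sweep_relative_intensity <- function(params,
                                     r0_grid = seq(0.1, 0.9, by = 0.1),
                                     price_ratio = 0.4,
                                     royalty_rate = 0.1234623,
                                     subsidy_coef = 0.065,
                                     ...) {
  if (any(r0_grid <= 0 | r0_grid >= 1) || any(diff(r0_grid) <= 0)) {
    stop("r0_grid must be strictly increasing within (0, 1)")
  }
  total <- params$v0_in + params$v0_out
  rows <- vector("list", length(r0_grid))
  for (i in seq_along(r0_grid)) {
    p2 <- params
    p2$v0_in <- r0_grid[i] * total
    p2$v0_out <- (1 - r0_grid[i]) * total
    cw <- compare_worlds(p2, price_ratio = price_ratio,
                         royalty_rate = royalty_rate,
                         subsidy_coef = subsidy_coef, ...)
    rows[[i]] <- .metric_row(r0_grid[i], cw$metrics)
  }
  .sweep_result("relative_intensity", r0_grid, do.call(rbind, rows), list())
}
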