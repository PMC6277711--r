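#' @export
print.mpp_trajectory <- function(x, ...) {
  sc <- attr(x, "scenario")
  tot <- trajectory_totals(x)
  cat(sprintf("MPP market trajectory (%s world, %d steps of %.4g y)\n",
              if (sc$pooled) "pooled" else "unpooled", nrow(x) - 1L, sc$dt))
  cat(sprintf("  final stocks: up %.1f, cp %.1f, rejected %.1f\n",
              x$up[nrow(x)], x$cp[nrow(x)], x$rejected[nrow(x)]))
  cat(sprintf("  cumulative: originator profit $%.4g, generic profit $%.4g\n",
              tot$profit_orig, tot$profit_gen))
  cat(sprintf("  government expenditure $%.4g (subsidy $%.4g, royalty $%.4g)\n",
              tot$gov_expenditure, tot$subsidy, tot$royalty))
  invisible(x)
}

#' @export
summary.mpp_trajectory <- function(object, ...) {
  tot <- trajectory_totals(object)
  structure(list(scenario = attr(object, "scenario"), totals = tot,
                 n_steps = nrow(object) - 1L,
                 n_truncated = attr(object, "n_truncated")),
            class = "summary.mpp_trajectory")
}

#' @export
print.summary.mpp_trajectory <- function(x, ...) {
  print(x$scenario)
  cat("Horizon totals:\n")
  for (nm in names(x$totals)) {
    cat(sprintf("  %-28s $%.6g\n", nm, x$totals[[nm]]))
  }
  if (x$n_truncated > 0L) {
    cat(sprintf("  (%d truncated flow steps)\n", x$n_truncated))
  }
  invisible(x)
}

#' Plot a market trajectory
#'
#' Two panels: patient stocks over time, and cumulative profits and
#' government expenditure.
#'
#' @param x An `mpp_trajectory`.
#' @param ... Passed to `matplot`.
#' @return `x`, invisibly.
#' @export
plot.mpp_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(x$t, cbind(x$up, x$cp, x$rejected), type = "l", lty = 1,
                    col = c("grey40", "firebrick", "steelblue"),
                    xlab = "years since launch", ylab = "persons",
                    main = "patient stocks", ...)
  graphics::legend("topleft", c("diagnosed (UP)", "in therapy (CP)", "rejected"),
                   col = c("grey40", "firebrick", "steelblue"), lty = 1, bty = "n")
  graphics::matplot(x$t, cbind(x$cum_profit_orig, x$cum_profit_gen,
                               x$cum_gov_expenditure),
                    type = "l", lty = 1,
                    col = c("black", "darkorange", "forestgreen"),
                    xlab = "years since launch", ylab = "dollars",
                    main = "cumulative ledgers")
  graphics::legend("topleft", c("originator profit", "generic profit",
                                "government expenditure"),
                   col = c("black", "darkorange", "forestgreen"), lty = 1,
                   bty = "n")
  invisible(x)
}

#' @export
print.mpp_comparison <- function(x, ...) {
  m <- x$metrics
  cat("Paired-world comparison (pooled vs unpooled)\n")
  cat(sprintf("  required subsidy   $%.6g   affordable subsidy $%.6g\n",
              m$required_subsidy, m$affordable_subsidy))
  cat(sprintf("  d_profit_orig $%.6g (%s)   d_gov $%.6g (%s)   d_profit_gen $%.6g\n",
              m$d_profit_orig, if (m$joins_orig) "joins" else "stays out",
              m$d_gov, if (m$joins_gov) "joins" else "stays out",
              m$d_profit_gen))
  invisible(x)
}

#' @export
print.mpp_sweep <- function(x, ...) {
  cat(sprintf("MPP sweep over %s (%d points, %.4g to %.4g)\n",
              x$lever, length(x$grid), min(x$grid), max(x$grid)))
  for (nm in names(x$thresholds)) {
    v <- x$thresholds[[nm]]
    cat(sprintf("  %s: %s\n", nm,
                if (is.na(v)) "none detected" else sprintf("%.6g", v)))
  }
  invisible(x)
}

#' Plot a sweep
#'
#' For price-ratio sweeps, plots required vs affordable subsidy; otherwise
#' plots the decision metrics over the lever grid. Detected thresholds are
#' drawn as vertical lines.
#'
#' @param x An `mpp_sweep`.
#' @param ... Passed to plotting primitives.
#' @return `x`, invisibly.
#' @export
plot.mpp_sweep <- function(x, ...) {
  tab <- x$table
  if (x$lever == "price_ratio") {
    graphics::matplot(x$grid, cbind(tab$required_subsidy, tab$affordable_subsidy),
                      type = "l", lty = 1, col = c("black", "forestgreen"),
                      xlab = "generic price ratio", ylab = "dollars",
                      main = "required vs affordable subsidy", ...)
    graphics::legend("topleft", c("required (originator shortfall)",
                                  "affordable (government savings)"),
                     col = c("black", "forestgreen"), lty = 1, bty = "n")
  } else {
    graphics::matplot(x$grid, cbind(tab$d_profit_orig, tab$d_profit_gen, tab$d_gov),
                      type = "l", lty = 1,
                      col = c("black", "darkorange", "forestgreen"),
                      xlab = x$lever, ylab = "dollars",
                      main = sprintf("decision metrics vs %s", x$lever), ...)
    graphics::legend("topleft", c("d_profit_orig", "d_profit_gen", "d_gov"),
                     col = c("black", "darkorange", "forestgreen"), lty = 1,
                     bty = "n")
  }
  for (v in unlist(x$thresholds)) {
    if (!is.na(v)) graphics::abline(v = v, lty = 2, col = "grey50")
  }
  invisible(x)
}

#' @export
print.mpp_interval <- function(x, ...) {
  cat(sprintf("Feasible pooling-subsidy interval at price ratio %.3g, royalty %.3g\n",
              x$price_ratio, x$royalty_rate))
  if (x$empty) {
    cat("  empty: no coefficient satisfies both parties\n")
  } else {
    cat(sprintf("  [%.3f, %.3f] (required $%.6g, affordable $%.6g)\n",
                x$s_lo, x$s_hi, x$required_subsidy, x$affordable_subsidy))
  }
  invisible(x)
}
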