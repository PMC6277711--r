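#' Prevailing prices at a given time
#'
#' The original price is constant in both worlds (the pool retains the
#' originator's price). The generic sells at `price_ratio * p_orig` from the
#' world's generic launch time; before launch `p_gen` is `NA`.
#'
#' @param scenario An `mpp_scenario` object.
#' @param t Time, years.
#' @param params An `mpp_params` object.
#' @return A list with `p_orig` and `p_gen` (dollars per patient-year;
#'   `p_gen` is `NA_real_` before the generic launch).
#' @export
step_prices <- function(scenario, t, params) {
  t_gen <- generic_launch_time(scenario)
  p_gen <- if (!is.na(t_gen) && t >= t_gen) {
    scenario$price_ratio * params$p_orig
  } else {
    NA_real_
  }
  list(p_orig = params$p_orig, p_gen = p_gen)
}

#' Generic launch time of a scenario
#'
#' `t_join + generic_lag` in pooled worlds, `patent_life + generic_lag`
#' otherwise; `NA` if it falls beyond the horizon.
#'
#' @param scenario An `mpp_scenario` object.
#' @return Years, or `NA_real_`.
#' @export
generic_launch_time <- function(scenario) {
  t_gen <- if (scenario$pooled) {
    scenario$t_join + scenario$generic_lag
  } else {
    scenario$patent_life + scenario$generic_lag
  }
  if (t_gen > scenario$horizon) NA_real_ else t_gen
}

#' Step revenues of originator and generic maker
#'
#' Treated patients on each product (the in-therapy stock split by the
#' within-class shares) times the annual price times the step length.
#'
#' @param cp In-therapy stock, persons.
#' @param orig_share,gen_share Within-market shares summing to the class
#'   share `m`.
#' @param prices List with `p_orig`, `p_gen` as from [step_prices()].
#' @param m Joint class share.
#' @param dt Step length, years.
#' @return List with `rev_orig`, `rev_gen` (dollars).
#' @export
step_revenues <- function(cp, orig_share, gen_share, prices, m, dt) {
  if (m <= 0) return(list(rev_orig = 0, rev_gen = 0))
  rev_orig <- cp * (orig_share / m) * prices$p_orig * dt
  rev_gen <- if (gen_share > 0) cp * (gen_share / m) * prices$p_gen * dt else 0
  list(rev_orig = rev_orig, rev_gen = rev_gen)
}

#' Originator per-step profit
#'
#' After-tax profit on sales net of production and marketing cost shares,
#' plus after-tax royalty income (in-pool only):
#' `(1 - psi) * (rev_orig * (1 - c_prod - c_mkt) + royalty_in)`.
#'
#' @param rev_orig Originator sales revenue this step, dollars.
#' @param royalty_in Royalty received this step (0 out of pool), dollars.
#' @param params An `mpp_params` object.
#' @param in_pool Logical.
#' @return Profit, dollars.
#' @export
step_profit_orig <- function(rev_orig, royalty_in, params, in_pool) {
  if (!in_pool) royalty_in <- 0
  (1 - params$psi) * (rev_orig * (1 - params$c_prod - params$c_mkt) + royalty_in)
}

#' Generic maker per-step profit and royalty
#'
#' In-pool, the licensed generic pays `royalty_rate * rev_gen` to the
#' originator while the licensed patent is alive; out-of-pool (post-expiry
#' entry) no royalty is ever due. Profit is after-tax revenue net of cost
#' shares and royalty. The engine passes `in_pool = FALSE` for in-pool steps
#' after patent expiry, when the license obligation has lapsed.
#'
#' @param rev_gen Generic sales revenue this step, dollars.
#' @param royalty_rate Fraction of generic revenue, in [0, 1).
#' @param params An `mpp_params` object.
#' @param in_pool Logical.
#' @return List with `profit` and `royalty_paid`, dollars.
#' @export
step_profit_gen <- function(rev_gen, royalty_rate, params, in_pool) {
  if (royalty_rate < 0 || royalty_rate >= 1) {
    stop("royalty_rate: must lie in [0, 1)")
  }
  royalty_paid <- if (in_pool) royalty_rate * rev_gen else 0
  profit <- (1 - params$psi) *
    (rev_gen * (1 - params$c_prod - params$c_mkt) - royalty_paid)
  list(profit = profit, royalty_paid = royalty_paid)
}

#' Government medical expenditure per step
#'
#' Drug purchases at prevailing prices for all treated patients on the focal
#' class, plus any pooling subsidy event falling on this step (nonzero only
#' at the join step of pooled worlds).
#'
#' @param rev_orig,rev_gen Purchases of each product this step, dollars
#'   (sales revenue equals purchase cost).
#' @param subsidy_event Subsidy disbursed this step, dollars (>= 0).
#' @return Expenditure, dollars.
#' @export
step_gov_expenditure <- function(rev_orig, rev_gen, subsidy_event = 0) {
  if (subsidy_event < 0) stop("subsidy_event: must be >= 0")
  rev_orig + rev_gen + subsidy_event
}
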