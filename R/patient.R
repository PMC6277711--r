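#' Incidence inflow of eligible diagnosed patients
#'
#' New patients entering the diagnosed-untreated stock over one step: the
#' population-level incidence filtered through the eligibility funnel
#' (affordable share `sigma`, diagnostic rate `phi`, outpatient rate
#' `rho_out`, treatment rate `eps_treat`), linear in the step length.
#'
#' @param params An `mpp_params` object.
#' @param dt Step length, years (> 0).
#' @return Persons entering the diagnosed stock during `dt`.
#' @export
incidence_inflow <- function(params, dt) {
  if (dt <= 0) stop("dt: must be > 0")
  params$population * params$morbidity *
    params$sigma * params$phi * params$rho_out * params$eps_treat * dt
}

#' Drug attraction index
#'
#' A [0, 1] index scaling patient adoption of the focal drug class,
#' determined by the originator's relative patent intensity and the class
#' average price level:
#' `A = r_in^gamma_r * min(1, ref_price / avg_price)^gamma_p`.
#' It is non-decreasing in `r_in` and non-increasing in `avg_price`; prices
#' at or below `ref_price` no longer limit adoption (the price term
#' saturates at 1).
#'
#' @param r_in Relative patent intensity, in [0, 1].
#' @param avg_price Average price of the focal drug class, dollars per
#'   patient-year (> 0).
#' @param ref_price Reference affordability price, dollars per
#'   patient-year (> 0).
#' @param gamma_r,gamma_p Non-negative attraction exponents.
#' @return Attraction in [0, 1].
#' @export
drug_attraction <- function(r_in, avg_price, ref_price, gamma_r, gamma_p) {
  if (any(avg_price <= 0) || any(ref_price <= 0)) {
    stop("prices must be > 0")
  }
  if (any(r_in < 0) || any(r_in > 1)) stop("r_in: must lie in [0, 1]")
  a <- r_in^gamma_r * pmin(1, ref_price / avg_price)^gamma_p
  pmin(1, pmax(0, a))
}

#' Potential sales volume per step
#'
#' The potential sales volume of the focal drug class over one 2-month
#' period: `pp = m * delta * (alpha * up + beta * cp)`, where `alpha`
#' captures prescription guidance acting on diagnosed-untreated patients and
#' `beta` word-of-mouth from patients in therapy, and `delta` indicates
#' whether the drug class is marketed at all.
#'
#' @param m Joint market share of the drug class, in [0, 1].
#' @param delta 0/1 marketing indicator.
#' @param alpha,beta Per-period adoption coefficients.
#' @param up Diagnosed-untreated stock, persons.
#' @param cp In-therapy stock, persons.
#' @return Persons per 2-month period.
#' @export
potential_sales <- function(m, delta, alpha, beta, up, cp) {
  stopifnot(delta %in% c(0, 1))
  if (any(c(m, alpha, beta, up, cp) < 0)) stop("inputs must be non-negative")
  m * delta * (alpha * up + beta * cp)
}

#' Market-share split between originator and generic
#'
#' Before the generic launches the originator holds the full class share
#' `m`. After launch the generic share ramps linearly from 0 to `0.7 * m`
#' over six months and stays there; the originator holds the remainder, so
#' the shares always sum to `m`.
#'
#' @param t_since_generic_launch Years since the generic launch (negative
#'   before launch); may be a vector.
#' @param m Joint class share, in [0, 1].
#' @return A list with components `orig_share` and `gen_share`.
#' @examples
#' generic_share_split(0.5, 0.25)$gen_share # 0.7 * 0.25
#' @export
generic_share_split <- function(t_since_generic_launch, m) {
  if (m < 0 || m > 1) stop("m: must lie in [0, 1]")
  ramp <- pmin(1, pmax(0, t_since_generic_launch / 0.5))
  gen <- 0.7 * m * ramp
  list(orig_share = m - gen, gen_share = gen)
}

#' Initial patient state
#'
#' @param up0 Initial diagnosed-untreated stock, persons.
#' @return A named list of stocks (`up`, `cp`, `rejected`), cumulative exits
#'   (`cum_suspended`, `cum_dead`), cumulative inflow bookkeeping
#'   (`cum_inflow`) and the count of flow truncations (`n_truncated`).
#' @export
patient_state <- function(up0 = 0) {
  list(up = up0, cp = 0, rejected = 0,
       cum_suspended = 0, cum_dead = 0,
       cum_inflow = 0, n_truncated = 0L)
}

#' Advance the patient-flow model by one Euler step
#'
#' One explicit Euler step of the stock-flow system. Flows are computed from
#' start-of-step stocks: rejected patients retreat at rate `zz` per year;
#' the potential sales volume `pp` leaves the diagnosed stock, a fraction
#' `attraction` starting therapy and the remainder moving to the rejected
#' stock; patients in therapy die with hazard `log(2)/omega` (exponential
#' survival with median `omega`) and suspend therapy with hazard
#' `-log(1-z)/omega` (lifetime suspension probability `z` realised over the
#' median survival window). Outflows larger than the available stock are
#' truncated proportionally (counted in `n_truncated`); stocks never go
#' negative.
#'
#' @param state A patient state as returned by [patient_state()] or a
#'   previous step.
#' @param inflow New eligible diagnosed patients this step, persons.
#' @param attraction Drug attraction in [0, 1] (see [drug_attraction()]).
#' @param delta 0/1 marketing indicator.
#' @param params An `mpp_params` object.
#' @param dt Step length, years.
#' @return A list with `state` (the advanced state) and `flows` (named
#'   vector: `pp`, `cp_flow`, `declined`, `retreat`, `dp`, `ccp`,
#'   `rej_death`).
#' @export
step_patient_flow <- function(state, inflow, attraction, delta, params, dt) {
  if (dt <= 0) stop("dt: must be > 0")
  lambda_death <- log(2) / params$omega
  h_susp <- -log(1 - params$z) / params$omega

  truncated <- FALSE
  # rejected stock: retreatment and (optionally) death
  retreat <- params$zz * state$rejected * dt
  rej_death <- if (params$rejected_mortality) lambda_death * state$rejected * dt else 0
  out_rej <- retreat + rej_death
  if (out_rej > state$rejected && out_rej > 0) {
    f <- state$rejected / out_rej
    retreat <- retreat * f
    rej_death <- rej_death * f
    truncated <- TRUE
  }

  # diagnosed stock: potential sales leave; alpha/beta are per base_period
  pp <- potential_sales(params$m_share, delta, params$alpha, params$beta,
                        state$up, state$cp) * (dt / params$base_period)
  if (pp > state$up) {
    pp <- state$up
    truncated <- TRUE
  }
  cp_flow <- attraction * pp
  declined <- pp - cp_flow

  # in-therapy stock: death and suspension
  dp <- lambda_death * state$cp * dt
  ccp <- h_susp * state$cp * dt
  out_cp <- dp + ccp
  if (out_cp > state$cp && out_cp > 0) {
    f <- state$cp / out_cp
    dp <- dp * f
    ccp <- ccp * f
    truncated <- TRUE
  }

  new <- state
  new$up <- state$up + inflow + retreat - pp
  new$cp <- state$cp + cp_flow - dp - ccp
  new$rejected <- state$rejected + declined - retreat - rej_death
  new$cum_suspended <- state$cum_suspended + ccp
  new$cum_dead <- state$cum_dead + dp + rej_death
  new$cum_inflow <- state$cum_inflow + inflow
  if (truncated) {
    new$n_truncated <- state$n_truncated + 1L
    warning("patient flow truncated at stock boundary", call. = FALSE)
  }
  # guard against rounding-induced negatives
  new$up <- max(new$up, 0)
  new$cp <- max(new$cp, 0)
  new$rejected <- max(new$rejected, 0)

  list(
    state = new,
    flows = c(pp = pp, cp_flow = cp_flow, declined = declined,
              retreat = retreat, dp = dp, ccp = ccp, rej_death = rej_death)
  )
}
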