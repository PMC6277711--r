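#' Event schedule of a scenario
#'
#' The ordered timeline of a world: drug launch, MPP entry and licensed
#' generic launch (pooled worlds), patent expiry, post-expiry generic launch
#' (unpooled worlds) and horizon end. Events falling beyond the horizon are
#' dropped with a notice.
#'
#' @param scenario An `mpp_scenario` object.
#' @return A data.frame with columns `time` (years) and `kind`, ordered by
#'   time, of class `mpp_schedule`.
#' @export
build_schedule <- function(scenario) {
  validate_scenario(scenario)
  ev <- data.frame(
    time = scenario$t_launch,
    kind = "launch",
    stringsAsFactors = FALSE
  )
  if (scenario$pooled) {
    ev <- rbind(ev, data.frame(
      time = c(scenario$t_join, scenario$t_join + scenario$generic_lag),
      kind = c("mpp_join", "generic_launch_in_pool")
    ))
  }
  ev <- rbind(ev, data.frame(time = scenario$patent_life, kind = "patent_expiry"))
  if (!scenario$pooled) {
    ev <- rbind(ev, data.frame(
      time = scenario$patent_life + scenario$generic_lag,
      kind = "generic_launch_post_expiry"
    ))
  }
  dropped <- ev[ev$time > scenario$horizon, , drop = FALSE]
  if (nrow(dropped)) {
    message(sprintf(
      "dropping %d event(s) beyond horizon %g y: %s",
      nrow(dropped), scenario$horizon,
      paste(sprintf("%s@%gy", dropped$kind, dropped$time), collapse = ", ")
    ))
  }
  ev <- ev[ev$time <= scenario$horizon, , drop = FALSE]
  ev <- rbind(ev, data.frame(time = scenario$horizon, kind = "horizon_end"))
  ev <- ev[order(ev$time), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("mpp_schedule", "data.frame")
  ev
}

#' Simulate one world
#'
#' Advances patent value, patient stocks and the economic ledger over the
#' scenario horizon with an explicit Euler step. Within each step, in order:
#' events due at the step start are applied (the pooling subsidy is booked
#' at the join step), patent values and attraction are evaluated, prices and
#' within-class shares are set, patient flows are stepped, and revenues and
#' ledgers are accumulated from start-of-step stocks. The run is fully
#' deterministic: identical inputs give identical trajectories.
#'
#' @param scenario An `mpp_scenario` object.
#' @param params An `mpp_params` object.
#' @return An `mpp_trajectory`: a data.frame with one row per step boundary
#'   (`horizon/dt + 1` rows). Stock and cumulative columns are valued at
#'   time `t`; flow and per-step economic columns cover the step starting at
#'   `t` (zero on the final row). Attributes `scenario`, `params` and
#'   `schedule` carry the inputs.
#' @examples
#' traj <- simulate_market(default_scenario(pooled = TRUE), mpp_params())
#' tail(traj[, c("t", "cp", "cum_gov_expenditure")], 3)
#' @export
simulate_market <- function(scenario, params) {
  validate_scenario(scenario)
  validate_params(params)

  dt <- scenario$dt
  n <- as.integer(round(scenario$horizon / dt))
  tgrid <- seq(0, by = dt, length.out = n + 1L)
  t_gen <- generic_launch_time(scenario)
  time_const <- params$tau + 1 / params$d
  lambda_death <- log(2) / params$omega
  h_susp <- -log(1 - params$z) / params$omega
  m <- params$m_share
  cc <- params$c_prod + params$c_mkt
  inflow <- incidence_inflow(params, dt)
  join_step <- if (scenario$pooled) {
    as.integer(round(scenario$t_join / dt))
  } else {
    NA_integer_
  }
  r_in <- relative_intensity(params$v0_in, params$v0_out)

  cols <- c(
    "t", "v_in", "v_out", "r_in", "attraction",
    "up", "cp", "rejected", "cum_suspended", "cum_dead",
    "pp", "cp_flow", "orig_share", "gen_share", "p_orig", "p_gen",
    "rev_orig", "rev_gen", "profit_orig", "profit_gen", "royalty",
    "subsidy", "gov_expenditure",
    "cum_rev_orig", "cum_rev_gen", "cum_profit_orig", "cum_profit_gen",
    "cum_royalty", "cum_subsidy", "cum_gov_expenditure", "cum_tax"
  )
  out <- matrix(0, nrow = n + 1L, ncol = length(cols),
                dimnames = list(NULL, cols))
  out[, "t"] <- tgrid
  out[, "p_orig"] <- params$p_orig
  out[, "p_gen"] <- NA_real_

  up <- params$up0; cp <- 0; rejected <- 0
  cum_susp <- 0; cum_dead <- 0; cum_inflow <- 0; n_trunc <- 0L
  c_rev_o <- 0; c_rev_g <- 0; c_pr_o <- 0; c_pr_g <- 0
  c_roy <- 0; c_sub <- 0; c_gov <- 0; c_tax <- 0

  one_minus_psi <- 1 - params$psi

  for (k in seq_len(n + 1L) - 1L) {
    t <- tgrid[k + 1L]
    i <- k + 1L

    v_in <- params$v0_in * exp(-t / time_const)
    v_out <- params$v0_out * exp(-t / time_const)

    gen_live <- !is.na(t_gen) && t >= t_gen
    if (gen_live) {
      # share ramp sampled at the step midpoint: exact step-average of the
      # linear ramp, so cumulative ledgers are insensitive to the step size
      sh <- generic_share_split(t - t_gen + dt / 2, m)
      p_gen <- scenario$price_ratio * params$p_orig
    } else {
      sh <- list(orig_share = m, gen_share = 0)
      p_gen <- NA_real_
    }
    avg_price <- if (gen_live && m > 0) {
      (sh$orig_share * params$p_orig + sh$gen_share * p_gen) / m
    } else {
      params$p_orig
    }
    attraction <- drug_attraction(r_in, avg_price, params$p_ref,
                                  params$gamma_r, params$gamma_p)
    delta <- if (t >= scenario$t_launch) 1 else 0

    out[i, "v_in"] <- v_in
    out[i, "v_out"] <- v_out
    out[i, "r_in"] <- r_in
    out[i, "attraction"] <- attraction
    out[i, "up"] <- up
    out[i, "cp"] <- cp
    out[i, "rejected"] <- rejected
    out[i, "cum_suspended"] <- cum_susp
    out[i, "cum_dead"] <- cum_dead
    out[i, "orig_share"] <- sh$orig_share
    out[i, "gen_share"] <- sh$gen_share
    out[i, "p_gen"] <- p_gen
    out[i, "cum_rev_orig"] <- c_rev_o
    out[i, "cum_rev_gen"] <- c_rev_g
    out[i, "cum_profit_orig"] <- c_pr_o
    out[i, "cum_profit_gen"] <- c_pr_g
    out[i, "cum_royalty"] <- c_roy
    out[i, "cum_subsidy"] <- c_sub
    out[i, "cum_gov_expenditure"] <- c_gov
    out[i, "cum_tax"] <- c_tax

    if (k == n) break # final boundary: no step follows

    # ---- patient flows over [t, t + dt), from start-of-step stocks ----
    retreat <- params$zz * rejected * dt
    rej_death <- if (params$rejected_mortality) lambda_death * rejected * dt else 0
    out_rej <- retreat + rej_death
    if (out_rej > rejected && out_rej > 0) {
      f <- rejected / out_rej; retreat <- retreat * f; rej_death <- rej_death * f
      n_trunc <- n_trunc + 1L
    }
    pp <- m * delta * (params$alpha * up + params$beta * cp) *
      (dt / params$base_period)
    if (pp > up) { pp <- up; n_trunc <- n_trunc + 1L }
    cp_flow <- attraction * pp
    declined <- pp - cp_flow
    dp <- lambda_death * cp * dt
    ccp <- h_susp * cp * dt
    out_cp <- dp + ccp
    if (out_cp > cp && out_cp > 0) {
      f <- cp / out_cp; dp <- dp * f; ccp <- ccp * f
      n_trunc <- n_trunc + 1L
    }

    # ---- economics over the step, from start-of-step stocks ----
    rev_orig <- if (m > 0) cp * (sh$orig_share / m) * params$p_orig * dt else 0
    rev_gen <- if (gen_live && m > 0) cp * (sh$gen_share / m) * p_gen * dt else 0
    # license fees derive from the patent: due only while it is alive
    royalty <- if (scenario$pooled && t < scenario$patent_life) {
      scenario$royalty_rate * rev_gen
    } else {
      0
    }
    gross_orig <- rev_orig * (1 - cc) + royalty
    gross_gen <- rev_gen * (1 - cc) - royalty
    profit_orig <- one_minus_psi * gross_orig
    profit_gen <- one_minus_psi * gross_gen
    tax <- params$psi * (gross_orig + gross_gen)
    subsidy <- if (!is.na(join_step) && k == join_step) {
      pooling_subsidy(scenario$subsidy_coef, params$v0_in)
    } else {
      0
    }
    gov <- step_gov_expenditure(rev_orig, rev_gen, subsidy)

    out[i, "pp"] <- pp
    out[i, "cp_flow"] <- cp_flow
    out[i, "rev_orig"] <- rev_orig
    out[i, "rev_gen"] <- rev_gen
    out[i, "profit_orig"] <- profit_orig
    out[i, "profit_gen"] <- profit_gen
    out[i, "royalty"] <- royalty
    out[i, "subsidy"] <- subsidy
    out[i, "gov_expenditure"] <- gov

    # ---- advance stocks ----
    up <- max(up + inflow + retreat - pp, 0)
    cp <- max(cp + cp_flow - dp - ccp, 0)
    rejected <- max(rejected + declined - retreat - rej_death, 0)
    cum_susp <- cum_susp + ccp
    cum_dead <- cum_dead + dp + rej_death
    cum_inflow <- cum_inflow + inflow
    c_rev_o <- c_rev_o + rev_orig
    c_rev_g <- c_rev_g + rev_gen
    c_pr_o <- c_pr_o + profit_orig
    c_pr_g <- c_pr_g + profit_gen
    c_roy <- c_roy + royalty
    c_sub <- c_sub + subsidy
    c_gov <- c_gov + gov
    c_tax <- c_tax + tax
  }

  traj <- as.data.frame(out)
  attr(traj, "scenario") <- scenario
  attr(traj, "params") <- params
  attr(traj, "schedule") <- build_schedule(scenario)
  attr(traj, "cum_inflow") <- cum_inflow
  attr(traj, "n_truncated") <- n_trunc
  if (n_trunc > 0L) {
    warning(sprintf("%d patient flow(s) truncated at stock boundaries", n_trunc),
            call. = FALSE)
  }
  class(traj) <- c("mpp_trajectory", "data.frame")
  traj
}

#' Cumulative totals of a trajectory
#'
#' @param traj An `mpp_trajectory`.
#' @return Named list of horizon totals: originator and generic cumulative
#'   profit, royalty, subsidy, government expenditure with and without the
#'   subsidy.
#' @export
trajectory_totals <- function(traj) {
  last <- traj[nrow(traj), ]
  list(
    profit_orig = last$cum_profit_orig,
    profit_gen = last$cum_profit_gen,
    royalty = last$cum_royalty,
    subsidy = last$cum_subsidy,
    gov_expenditure = last$cum_gov_expenditure,
    gov_expenditure_pre_subsidy = last$cum_gov_expenditure - last$cum_subsidy,
    tax = last$cum_tax
  )
}

#' Paired-world comparison
#'
#' Runs the pooled and unpooled worlds on identical parameters and the same
#' levers, and returns the decision metrics at the horizon: the originator's
#' cumulative profit difference (subsidy included), the generic maker's
#' profit difference, the government's expenditure savings (subsidy
#' deducted), the pre-subsidy required subsidy (originator shortfall) and
#' affordable subsidy (government savings), and the resulting join flags.
#'
#' @param params An `mpp_params` object.
#' @param price_ratio,royalty_rate,subsidy_coef Policy levers; defaults from
#'   [mpp_scenario()].
#' @param ... Further shared scenario fields passed to both worlds.
#' @return An `mpp_comparison` object: list with `pooled`, `unpooled`
#'   trajectories and `metrics`.
#' @examples
#' cw <- compare_worlds(mpp_params(), price_ratio = 0.3)
#' cw$metrics$joins_gov
#' @export
compare_worlds <- function(params,
                           price_ratio = 0.4,
                           royalty_rate = 0.1234623,
                           subsidy_coef = 0.065,
                           ...) {
  sc_in <- mpp_scenario(pooled = TRUE, price_ratio = price_ratio,
                        royalty_rate = royalty_rate,
                        subsidy_coef = subsidy_coef, ...)
  sc_out <- mpp_scenario(pooled = FALSE, price_ratio = price_ratio,
                         royalty_rate = royalty_rate,
                         subsidy_coef = subsidy_coef, ...)
  t_in <- simulate_market(sc_in, params)
  t_out <- simulate_market(sc_out, params)
  metrics <- decision_metrics(t_in, t_out, subsidy_coef, params)
  res <- list(pooled = t_in, unpooled = t_out, metrics = metrics)
  class(res) <- "mpp_comparison"
  res
}

#' Decision metrics from a pair of trajectories
#'
#' @param traj_pooled,traj_unpooled Trajectories of the pooled and unpooled
#'   worlds on identical parameters.
#' @param subsidy_coef Subsidy coefficient used for the join flags.
#' @param params The shared `mpp_params`.
#' @return Named list of decision metrics (dollars; `joins_*` logical).
#' @export
decision_metrics <- function(traj_pooled, traj_unpooled, subsidy_coef, params) {
  ti <- trajectory_totals(traj_pooled)
  to <- trajectory_totals(traj_unpooled)
  subsidy <- pooling_subsidy(subsidy_coef, params$v0_in)
  required <- to$profit_orig - ti$profit_orig # pre-subsidy shortfall
  affordable <- to$gov_expenditure_pre_subsidy - ti$gov_expenditure_pre_subsidy
  d_profit_orig <- ti$profit_orig + subsidy - to$profit_orig
  d_profit_gen <- ti$profit_gen - to$profit_gen
  d_gov <- affordable - subsidy
  list(
    required_subsidy = required,
    affordable_subsidy = affordable,
    subsidy = subsidy,
    d_profit_orig = d_profit_orig,
    d_profit_gen = d_profit_gen,
    d_gov = d_gov,
    joins_orig = d_profit_orig >= 0,
    joins_gov = d_gov >= 0
  )
}
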