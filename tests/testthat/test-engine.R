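test_that("event schedules match the scenario timeline", {
  ev <- build_schedule(default_scenario(TRUE))
  expect_equal(ev$time[ev$kind == "generic_launch_in_pool"], 2)
  expect_equal(ev$time[ev$kind == "patent_expiry"], 12)
  expect_false("generic_launch_post_expiry" %in% ev$kind)
  ev <- build_schedule(default_scenario(FALSE))
  expect_equal(ev$time[ev$kind == "generic_launch_post_expiry"], 14)
  # events beyond the horizon are dropped with a notice
  expect_message(
    ev <- build_schedule(mpp_scenario(FALSE, horizon = 10, patent_life = 10,
                                      dt = 1 / 6)),
    "dropping"
  )
  expect_false("generic_launch_post_expiry" %in% ev$kind)
})

test_that("trajectories have one record per step boundary, strictly in time", {
  traj <- quiet_sim(default_scenario(TRUE))
  expect_equal(nrow(traj), 97)
  expect_equal(diff(traj$t), rep(1 / 6, 96), tolerance = 1e-12)
})

test_that("an empty epidemic yields zero market and subsidy-only expenditure", {
  p <- mpp_params(morbidity = 0)
  traj <- quiet_sim(mpp_scenario(TRUE, subsidy_coef = 0.05), p)
  expect_true(all(traj[, c("up", "cp", "rejected", "rev_orig", "rev_gen")] == 0))
  expect_equal(max(traj$cum_gov_expenditure), pooling_subsidy(0.05, p$v0_in))
})

test_that("simulation is deterministic", {
  t1 <- quiet_sim(default_scenario(TRUE))
  t2 <- quiet_sim(default_scenario(TRUE))
  expect_identical(t1, t2)
})

test_that("stocks are non-negative and persons are conserved at every step", {
  for (pooled in c(TRUE, FALSE)) {
    for (ratio in c(0.15, 0.4, 0.9)) {
      traj <- quiet_sim(mpp_scenario(pooled, price_ratio = ratio))
      expect_true(all(traj$up >= 0 & traj$cp >= 0 & traj$rejected >= 0))
      resid <- conservation_residual(traj)
      expect_lt(max(abs(resid)), 1e-6 * max(traj$up))
    }
  }
})

test_that("worlds coincide when all levers are neutral and timing is forced equal", {
  p <- default_params
  # licensed generic delayed to year 14 so both worlds launch generics together
  sc_in <- mpp_scenario(TRUE, price_ratio = 1, royalty_rate = 0,
                        subsidy_coef = 0, generic_lag = 14)
  sc_out <- mpp_scenario(FALSE, price_ratio = 1, royalty_rate = 0,
                         subsidy_coef = 0, generic_lag = 2)
  t_in <- quiet_sim(sc_in, p)
  t_out <- quiet_sim(sc_out, p)
  expect_equal(trajectory_totals(t_in)$gov_expenditure,
               trajectory_totals(t_out)$gov_expenditure, tolerance = 1e-12)
  expect_equal(trajectory_totals(t_in)$profit_orig,
               trajectory_totals(t_out)$profit_orig, tolerance = 1e-12)
  expect_equal(t_in$cp, t_out$cp, tolerance = 1e-12)
})

test_that("engine steps agree with the exported patient-flow operation", {
  p <- default_params
  sc <- default_scenario(TRUE)
  traj <- quiet_sim(sc, p)
  st <- patient_state(up0 = p$up0)
  inflow <- incidence_inflow(p, sc$dt)
  for (k in 1:12) {
    res <- suppressWarnings(
      step_patient_flow(st, inflow, traj$attraction[k], 1, p, sc$dt)
    )
    st <- res$state
    expect_equal(st$up, traj$up[k + 1], tolerance = 1e-12)
    expect_equal(st$cp, traj$cp[k + 1], tolerance = 1e-12)
    expect_equal(st$rejected, traj$rejected[k + 1], tolerance = 1e-12)
  }
})

test_that("patient stocks are exactly linear in population", {
  p2 <- mpp_params(population = 2 * default_params$population)
  t1 <- quiet_sim(default_scenario(TRUE))
  t2 <- quiet_sim(default_scenario(TRUE), p2)
  expect_equal(t2$up, 2 * t1$up, tolerance = 1e-12)
  expect_equal(t2$cp, 2 * t1$cp, tolerance = 1e-12)
  expect_equal(t2$cum_gov_expenditure[97] - t2$cum_subsidy[97],
               2 * (t1$cum_gov_expenditure[97] - t1$cum_subsidy[97]),
               tolerance = 1e-12)
})

test_that("halving the step changes cumulative ledgers by less than 2%", {
  for (pooled in c(TRUE, FALSE)) {
    a <- trajectory_totals(quiet_sim(mpp_scenario(pooled)))
    b <- trajectory_totals(quiet_sim(mpp_scenario(pooled, dt = 1 / 12)))
    for (f in c("profit_orig", "profit_gen", "gov_expenditure")) {
      expect_lt(abs(a[[f]] - b[[f]]) / abs(b[[f]]), 0.02)
    }
  }
})

test_that("paired-world metrics difference the two ledgers consistently", {
  cw <- compare_worlds(default_params, price_ratio = 0.3, royalty_rate = 0.05,
                       subsidy_coef = 0.06)
  m <- cw$metrics
  ti <- trajectory_totals(cw$pooled)
  to <- trajectory_totals(cw$unpooled)
  expect_equal(m$required_subsidy, to$profit_orig - ti$profit_orig)
  expect_equal(m$affordable_subsidy,
               to$gov_expenditure_pre_subsidy - ti$gov_expenditure_pre_subsidy)
  expect_equal(m$subsidy, 0.06 * default_params$v0_in)
  expect_equal(m$d_profit_orig, m$subsidy - m$required_subsidy)
  expect_equal(m$d_gov, m$affordable_subsidy - m$subsidy)
  expect_identical(m$joins_orig, m$d_profit_orig >= 0)
  expect_identical(m$joins_gov, m$d_gov >= 0)
})
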