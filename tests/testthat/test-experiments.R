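test_that("find_crossing interpolates the first sign change", {
  g <- seq(0.10, 0.60, by = 0.002)
  expect_equal(find_crossing(g, g - 0.358), 0.358)
  expect_true(is.na(find_crossing(g, g + 1)))
  expect_equal(find_crossing(c(0, 1), c(-1, 1)), 0.5)
  # exact zero at a grid point is returned as-is
  expect_equal(find_crossing(c(0, 1, 2), c(-1, 0, 1)), 1)
  expect_error(find_crossing(1:3, 1:2), "length")
  expect_error(find_crossing(c(1, 1, 2), c(1, -1, 1)), "increasing")
})

test_that("find_crossing agrees with a 10x-denser grid scan", {
  set.seed(11)
  for (rep in 1:20) {
    a <- runif(1, 0.5, 3); b <- runif(1, 0.1, 0.9)
    f <- function(x) a * (x - b) + 0.2 * sin(3 * x) * a
    coarse <- seq(0, 1, by = 0.02)
    dense <- seq(0, 1, by = 0.002)
    xc <- find_crossing(coarse, f(coarse))
    xd <- find_crossing(dense, f(dense))
    if (!is.na(xc) && !is.na(xd)) {
      expect_lt(abs(xc - xd), 0.02) # within one coarse-grid spacing
    }
  }
})

# coarse grids keep the sweep loops quick; monotone structure is grid-free
price_grid <- seq(0.10, 0.60, by = 0.02)
roy_grid <- seq(0, 0.60, by = 0.03)

test_that("price-ratio sweep: savings fall with the ratio and cross required once", {
  sw <- sweep_price_ratio(default_params, grid = price_grid)
  tab <- sw$table
  expect_true(all(diff(tab$affordable_subsidy) < 0))
  gap <- tab$affordable_subsidy - tab$required_subsidy
  expect_true(all(diff(gap) < 0))
  x <- sw$thresholds$price_ratio_crossing
  expect_false(is.na(x))
  # below the crossing the government can out-pay the originator's shortfall
  expect_true(all(gap[tab$value < x] > 0))
  expect_true(all(gap[tab$value > x] < 0))
})

test_that("royalty sweep: government invariant, generic falling, originator rising", {
  sw <- sweep_royalty(default_params, grid = roy_grid)
  tab <- sw$table
  expect_lt(diff(range(tab$d_gov)), 1e-6)
  expect_lt(diff(range(tab$gov_expenditure_pooled)), 1e-6)
  expect_true(all(diff(tab$d_profit_gen) < 0))
  expect_true(all(diff(tab$d_profit_orig) > 0))
})

test_that("royalty conservation: originator and generic ledgers cancel exactly", {
  p <- default_params
  cc <- p$c_prod + p$c_mkt
  for (roy in c(0, 0.2, 0.45)) {
    traj <- quiet_sim(mpp_scenario(TRUE, royalty_rate = roy), p)
    tot <- trajectory_totals(traj)
    # royalty transfers cancel in the joint profit, leaving the taxed margin
    expect_equal(tot$profit_orig + tot$profit_gen,
                 (1 - p$psi) * (1 - cc) *
                   (traj$cum_rev_orig[97] + traj$cum_rev_gen[97]),
                 tolerance = 1e-12)
    # royalty is only collected while the patent is alive
    expect_equal(tot$royalty,
                 roy * sum(traj$rev_gen[traj$t < 12]), tolerance = 1e-12)
  }
})

test_that("feasible interval endpoints satisfy the join predicates sharply", {
  fi <- feasible_subsidy_interval(default_params, price_ratio = 0.30,
                                  royalty_rate = 0.05,
                                  s_grid = seq(0, 0.2, by = 0.005))
  expect_false(fi$empty)
  tab <- fi$table
  expect_true(all(tab$feasible[tab$subsidy_coef >= fi$s_lo &
                                 tab$subsidy_coef <= fi$s_hi]))
  below <- tab$subsidy_coef < fi$s_lo
  above <- tab$subsidy_coef > fi$s_hi
  expect_true(all(!tab$joins_orig[below]))
  expect_true(all(!tab$joins_gov[above]))
})

test_that("interval is empty above the price-ratio crossing and widens below", {
  sw <- sweep_price_ratio(default_params, grid = seq(0.30, 0.44, by = 0.02))
  x <- sw$thresholds$price_ratio_crossing
  fi_hi <- feasible_subsidy_interval(default_params, price_ratio = x + 0.04,
                                     royalty_rate = 0.05)
  expect_true(fi_hi$empty)
  widths <- vapply(c(0.15, 0.25, 0.35), function(r) {
    fi <- feasible_subsidy_interval(default_params, price_ratio = r,
                                    royalty_rate = 0.05)
    if (fi$empty) 0 else fi$s_hi - fi$s_lo
  }, numeric(1))
  expect_true(all(diff(widths) <= 0))
})

test_that("R&D scale: dynamics invariant, decision difference declining", {
  sw <- sweep_rd_scale(default_params, total_v0_grid = c(5e7, 1e8, 2e8, 4e8))
  tab <- sw$table
  # pre-subsidy shortfall is scale-invariant (relative intensity unchanged)
  expect_lt(diff(range(tab$required_subsidy)) / abs(tab$required_subsidy[1]), 1e-9)
  # out-minus-in difference including the subsidy (= -d_profit_orig)
  # declines with scale, so joining gets likelier for larger enterprises
  expect_true(all(diff(-tab$d_profit_orig) < 0))
  expect_true(all(diff(tab$required_subsidy_coef) < 0))
})

test_that("relative intensity: attraction and profit difference rise with r0", {
  r0 <- c(0.2, 0.4, 0.5, 0.6, 0.8)
  a0 <- drug_attraction(r0, default_params$p_orig, default_params$p_ref,
                        default_params$gamma_r, default_params$gamma_p)
  expect_true(all(diff(a0) > 0))
  sw <- sweep_relative_intensity(default_params, r0_grid = r0)
  expect_true(all(diff(sw$table$required_subsidy) >= 0))
  # the symmetric point reproduces the default-parameter comparison exactly
  base <- compare_worlds(default_params)
  mid <- sw$table[sw$table$value == 0.5, ]
  expect_equal(mid$required_subsidy, base$metrics$required_subsidy)
  expect_equal(mid$d_gov, base$metrics$d_gov)
})

test_that("sweeps are deterministic", {
  g <- seq(0.2, 0.5, by = 0.05)
  s1 <- sweep_price_ratio(default_params, grid = g)
  s2 <- sweep_price_ratio(default_params, grid = g)
  expect_identical(s1$table, s2$table)
  expect_identical(s1$thresholds, s2$thresholds)
})

test_that("detected thresholds are invariant to the population scale", {
  p2 <- mpp_params(population = 3 * default_params$population)
  g1 <- seq(0.30, 0.42, by = 0.004)
  x1 <- sweep_price_ratio(default_params, grid = g1)$thresholds$price_ratio_crossing
  x2 <- sweep_price_ratio(p2, grid = g1)$thresholds$price_ratio_crossing
  expect_equal(x1, x2, tolerance = 1e-9)
  g2 <- seq(0.28, 0.40, by = 0.004)
  y1 <- sweep_royalty(default_params, grid = g2)$thresholds$royalty_rate_ceiling
  y2 <- sweep_royalty(p2, grid = g2)$thresholds$royalty_rate_ceiling
  expect_equal(y1, y2, tolerance = 1e-9)
  # subsidy endpoints are dollar shortfalls over v0: invariant under joint
  # scaling of population and R&D investments
  p3 <- mpp_params(population = 3 * default_params$population,
                   v0_in = 3 * default_params$v0_in,
                   v0_out = 3 * default_params$v0_out)
  f1 <- feasible_subsidy_interval(default_params, 0.30, 0.05)
  f3 <- feasible_subsidy_interval(p3, 0.30, 0.05)
  expect_equal(f1$s_lo, f3$s_lo)
  expect_equal(f1$s_hi, f3$s_hi)
})
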