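# Shared fixtures: everything is generated in code.

default_params <- mpp_params()

# a cheap, fast scenario pair for property loops (coarser grid, short horizon
# only where the full horizon is not needed)
quiet_sim <- function(scenario, params = default_params) {
  suppressMessages(simulate_market(scenario, params))
}

# conservation residual of a trajectory: stocks + cumulative exits minus
# cumulative inflow (and initial stock), per row
conservation_residual <- function(traj) {
  params <- attr(traj, "params")
  sc <- attr(traj, "scenario")
  inflow_step <- incidence_inflow(params, sc$dt)
  k <- seq_len(nrow(traj)) - 1
  total <- traj$up + traj$cp + traj$rejected + traj$cum_suspended + traj$cum_dead
  total - (params$up0 + k * inflow_step)
}
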