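#' Write a trajectory to CSV
#'
#' Plain CSV, '.' decimal separator, no thousands separators, header row
#' always present; byte-identical across reruns of the same inputs.
#'
#' @param traj An `mpp_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(traj)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a sweep table to CSV
#'
#' @param sweep An `mpp_sweep`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  tab <- sweep$table
  names(tab)[names(tab) == "value"] <- sweep$lever
  utils::write.csv(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' Records the tool version, the fully resolved parameter set and scenario,
#' any grids, the output paths, and a content hash of the resolved inputs,
#' so every output file is traceable to exactly one invocation.
#'
#' @param params An `mpp_params`.
#' @param scenario An `mpp_scenario` or NULL.
#' @param grids Named list of grids used, or NULL.
#' @param outputs Character vector of output file paths.
#' @return A list of class `mpp_manifest`.
#' @export
run_manifest <- function(params, scenario = NULL, grids = NULL,
                         outputs = character(0)) {
  resolved <- list(
    params = unclass(params),
    scenario = if (is.null(scenario)) NULL else unclass(scenario),
    grids = grids
  )
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(resolved, tmp, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    tool = "mppdyn",
    version = as.character(utils::packageVersion("mppdyn")),
    inputs = resolved,
    input_hash = unname(tools::md5sum(tmp)),
    outputs = outputs
  )
  class(manifest) <- c("mpp_manifest", "list")
  manifest
}

#' @rdname run_manifest
#' @param manifest An `mpp_manifest`.
#' @param path Output path for the manifest JSON.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

.config_error <- function(msg) {
  stop(structure(class = c("mpp_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

.load_cfg_params <- function(config) {
  tryCatch(
    if (is.null(config)) mpp_params() else load_parameters(config),
    error = function(e) .config_error(conditionMessage(e))
  )
}

#' Parse a grid specification
#'
#' Grid specs are `start:stop:step` with `start < stop` and `step > 0`.
#'
#' @param spec A string like `"0.10:0.60:0.002"`.
#' @return Numeric grid.
#' @export
parse_grid_spec <- function(spec) {
  parts <- suppressWarnings(as.numeric(strsplit(spec, ":", fixed = TRUE)[[1]]))
  if (length(parts) != 3L || any(is.na(parts))) {
    .config_error(sprintf(
      "malformed grid spec '%s'; expected start:stop:step with numeric parts",
      spec
    ))
  }
  if (parts[1] >= parts[2] || parts[3] <= 0) {
    .config_error(sprintf(
      "malformed grid spec '%s': need start < stop and step > 0", spec
    ))
  }
  seq(parts[1], parts[2], by = parts[3])
}

#' Run one world and write its outputs
#'
#' Writes the trajectory CSV, a decision/ledger JSON and a run manifest into
#' `out_dir`.
#'
#' @param config Path to a YAML/JSON parameter config, a named list, or
#'   NULL for defaults.
#' @param pooled Logical; which world to run.
#' @param out_dir Output directory (created if needed).
#' @param ... Scenario overrides passed to [mpp_scenario()].
#' @return Invisibly, the list of written paths.
#' @export
cmd_run <- function(config = NULL, pooled = TRUE, out_dir = ".", ...) {
  params <- .load_cfg_params(config)
  scenario <- tryCatch(mpp_scenario(pooled = pooled, ...),
                       error = function(e) .config_error(conditionMessage(e)))
  traj <- simulate_market(scenario, params)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    trajectory = file.path(out_dir, "trajectory.csv"),
    totals = file.path(out_dir, "totals.json"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_trajectory_csv(traj, paths$trajectory)
  jsonlite::write_json(trajectory_totals(traj), paths$totals,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(run_manifest(params, scenario,
                              outputs = unlist(paths, use.names = FALSE)),
                 paths$manifest)
  invisible(paths)
}

#' Run the paired-world comparison and write its outputs
#'
#' @inheritParams cmd_run
#' @return Invisibly, the list of written paths.
#' @export
cmd_compare <- function(config = NULL, out_dir = ".", ...) {
  params <- .load_cfg_params(config)
  cw <- tryCatch(compare_worlds(params, ...),
                 error = function(e) .config_error(conditionMessage(e)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    pooled = file.path(out_dir, "trajectory_pooled.csv"),
    unpooled = file.path(out_dir, "trajectory_unpooled.csv"),
    metrics = file.path(out_dir, "decision_metrics.json"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_trajectory_csv(cw$pooled, paths$pooled)
  write_trajectory_csv(cw$unpooled, paths$unpooled)
  jsonlite::write_json(cw$metrics, paths$metrics, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_manifest(run_manifest(params, attr(cw$pooled, "scenario"),
                              outputs = unlist(paths, use.names = FALSE)),
                 paths$manifest)
  invisible(paths)
}

.sweep_levers <- c("price_ratio", "subsidy_coef", "royalty_rate",
                   "rd_scale", "relative_intensity")

#' Run a sweep and write its outputs
#'
#' @inheritParams cmd_run
#' @param lever One of `price_ratio`, `subsidy_coef`, `royalty_rate`,
#'   `rd_scale`, `relative_intensity`.
#' @param grid Numeric grid or a `start:stop:step` string.
#' @param price_ratio,royalty_rate Fixed levers where the sweep needs them.
#' @return Invisibly, the list of written paths.
#' @export
cmd_sweep <- function(config = NULL, lever, grid = NULL, out_dir = ".",
                      price_ratio = 0.4, royalty_rate = 0.1234623, ...) {
  if (!lever %in% .sweep_levers) {
    .config_error(sprintf("unknown lever '%s'; valid levers: %s",
                          lever, paste(.sweep_levers, collapse = ", ")))
  }
  params <- .load_cfg_params(config)
  if (is.character(grid)) grid <- parse_grid_spec(grid)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    sweep = file.path(out_dir, sprintf("sweep_%s.csv", lever)),
    thresholds = file.path(out_dir, "thresholds.json"),
    manifest = file.path(out_dir, "manifest.json")
  )
  if (lever == "subsidy_coef") {
    fi <- feasible_subsidy_interval(
      params, price_ratio = price_ratio, royalty_rate = royalty_rate,
      s_grid = if (is.null(grid)) seq(0, 0.20, by = 0.001) else grid, ...
    )
    utils::write.csv(fi$table, paths$sweep, row.names = FALSE, quote = FALSE)
    thresholds <- list(s_lo = fi$s_lo, s_hi = fi$s_hi, empty = fi$empty)
    grids <- list(subsidy_coef = fi$table$subsidy_coef)
  } else {
    sw <- switch(lever,
      price_ratio = sweep_price_ratio(
        params, grid = if (is.null(grid)) seq(0.10, 0.60, by = 0.002) else grid,
        royalty_rate = royalty_rate, ...
      ),
      royalty_rate = sweep_royalty(
        params, grid = if (is.null(grid)) seq(0, 0.60, by = 0.002) else grid,
        price_ratio = price_ratio, ...
      ),
      rd_scale = sweep_rd_scale(
        params,
        total_v0_grid = if (is.null(grid)) seq(2e7, 2e8, by = 2e7) else grid,
        price_ratio = price_ratio, royalty_rate = royalty_rate, ...
      ),
      relative_intensity = sweep_relative_intensity(
        params, r0_grid = if (is.null(grid)) seq(0.1, 0.9, by = 0.1) else grid,
        price_ratio = price_ratio, royalty_rate = royalty_rate, ...
      )
    )
    write_sweep_csv(sw, paths$sweep)
    thresholds <- if (length(sw$thresholds)) sw$thresholds else list(threshold = NULL)
    grids <- stats::setNames(list(sw$grid), lever)
  }
  jsonlite::write_json(thresholds, paths$thresholds, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  write_manifest(run_manifest(params, grids = grids,
                              outputs = unlist(paths, use.names = FALSE)),
                 paths$manifest)
  invisible(paths)
}

#' Reproduce a canned results experiment
#'
#' Canned grids for the five sweep experiments: 3 = price-ratio sweep,
#' 4 = feasible subsidy intervals over price ratios 0.15-0.35,
#' 5 = royalty sweep, 6 = R&D-scale sweep, 7 = relative-intensity sweep.
#'
#' @inheritParams cmd_run
#' @param figure Integer 3-7.
#' @return Invisibly, the written paths.
#' @export
cmd_reproduce <- function(config = NULL, figure, out_dir = ".") {
  figure <- as.integer(figure)
  if (!figure %in% 3:7) .config_error("figure must be one of 3, 4, 5, 6, 7")
  params <- .load_cfg_params(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (figure == 4) {
    ratios <- seq(0.15, 0.35, by = 0.05)
    rows <- lapply(ratios, function(r) {
      fi <- feasible_subsidy_interval(params, price_ratio = r,
                                      royalty_rate = 0.05)
      data.frame(price_ratio = r, s_lo = fi$s_lo, s_hi = fi$s_hi,
                 empty = fi$empty)
    })
    tab <- do.call(rbind, rows)
    path <- file.path(out_dir, "experiment4_subsidy_intervals.csv")
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
    write_manifest(run_manifest(params, grids = list(price_ratio = ratios),
                                outputs = path),
                   file.path(out_dir, "manifest.json"))
    return(invisible(list(table = path)))
  }
  lever <- switch(as.character(figure),
                  "3" = "price_ratio", "5" = "royalty_rate",
                  "6" = "rd_scale", "7" = "relative_intensity")
  cmd_sweep(config, lever = lever, out_dir = out_dir)
}
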