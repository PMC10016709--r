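#' Solver configuration
#'
#' Growth-time grid and inner-MIP settings for the two-stage algorithm.
#' The outer stage evaluates growth times `t_min, t_min + dt, ...` up to
#' `t_max`; the inner MIP at each grid point is solved to a relative
#' optimality gap of `mip_gap` (0 = proven optimality).
#'
#' @param t_min,t_max growth-time bounds in years, `0 < t_min <= t_max`.
#' @param dt grid step in years (default 0.02).
#' @param mip_gap relative MIP gap tolerance (default 0).
#' @param time_limit optional wall-clock limit in seconds per inner solve.
#' @return an object of class `solver_config`.
#' @export
solver_config <- function(t_min = 0.02, t_max = 1.0, dt = 0.02,
                          mip_gap = 0, time_limit = NULL) {
  stopifnot(is.numeric(t_min), is.numeric(t_max), is.numeric(dt),
            is.numeric(mip_gap))
  if (!(t_min > 0 && t_min <= t_max)) stop("need 0 < t_min <= t_max", call. = FALSE)
  if (dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  if (mip_gap < 0) stop("'mip_gap' must be >= 0", call. = FALSE)
  if (!is.null(time_limit) && (!is.numeric(time_limit) || time_limit <= 0)) {
    stop("'time_limit' must be NULL or > 0 seconds", call. = FALSE)
  }
  structure(list(t_min = t_min, t_max = t_max, dt = dt,
                 mip_gap = mip_gap, time_limit = time_limit),
            class = "solver_config")
}

#' Assemble a problem instance
#'
#' Bundles demand clusters, candidate facility sites, cost parameters, the
#' survival curve, the trip-cost matrix and solver settings into the single
#' object consumed by [two_stage_solve()], [build_mip()] and
#' [brute_force_oracle()]. The trip-cost matrix is computed from the
#' geometry when not supplied.
#'
#' @param clusters a [sweep_cluster()] result (set `I` with annual demands).
#' @param facilities candidate sites data.frame (`id`, `lat`, `lon`),
#'   default [default_ports()].
#' @param cost_params a [cost_params()].
#' @param survival a [survival_spec()].
#' @param config a [solver_config()].
#' @param trip_costs optional `|I| x |J|` $/trip matrix; computed via
#'   [trip_cost_matrix()] when `NULL`.
#' @return an object of class `problem_instance`.
#' @export
problem_instance <- function(clusters, facilities = default_ports(),
                             cost_params = reefplan::cost_params(),
                             survival = survival_spec(),
                             config = solver_config(),
                             trip_costs = NULL) {
  stopifnot(is.data.frame(clusters), "annual_demand" %in% names(clusters),
            is.data.frame(facilities), nrow(facilities) >= 1L,
            inherits(cost_params, "cost_params"),
            inherits(survival, "survival_spec"),
            inherits(config, "solver_config"))
  if (any(clusters$annual_demand < 0)) {
    stop("cluster demands must be >= 0", call. = FALSE)
  }
  if (is.null(trip_costs)) {
    trip_costs <- trip_cost_matrix(facilities, clusters, cost_params)
  }
  if (!is.matrix(trip_costs) ||
      nrow(trip_costs) != nrow(clusters) ||
      ncol(trip_costs) != nrow(facilities)) {
    stop("'trip_costs' must be an |I| x |J| matrix", call. = FALSE)
  }
  structure(list(clusters = clusters, facilities = facilities,
                 cost_params = cost_params, survival = survival,
                 config = config, trip_costs = trip_costs),
            class = "problem_instance")
}

#' Build an instance straight from reefs and ports
#'
#' Convenience pipeline: compute per-reef demand, sweep-cluster the reefs
#' under the vessel capacity, build the trip-cost matrix, and assemble the
#' [problem_instance()].
#'
#' @param reefs reef data.frame (`id`, `lat`, `lon`, `area_km2`).
#' @param facilities candidate sites, default [default_ports()].
#' @param demand a [demand_params()].
#' @param cost a [cost_params()].
#' @param survival a [survival_spec()].
#' @param config a [solver_config()].
#' @return a `problem_instance`.
#' @export
#' @examples
#' reefs <- generate_synthetic_reefs(synthetic_field_spec(n_reefs = 10, seed = 1))
#' inst <- build_instance(reefs)
#' nrow(inst$clusters)
build_instance <- function(reefs, facilities = default_ports(),
                           demand = demand_params(), cost = cost_params(),
                           survival = survival_spec(),
                           config = solver_config()) {
  clusters <- sweep_cluster(reefs, s_c = cost$s_c, params = demand)
  problem_instance(clusters, facilities, cost, survival, config)
}

#' @export
print.problem_instance <- function(x, ...) {
  cat(sprintf("Problem instance: %d clusters, %d candidate facilities\n",
              nrow(x$clusters), nrow(x$facilities)))
  cat(sprintf("  total annual demand: %.4g surviving units/yr\n",
              sum(x$clusters$annual_demand)))
  print(x$survival)
  cat(sprintf("  growth-time grid: [%g, %g] step %g\n",
              x$config$t_min, x$config$t_max, x$config$dt))
  invisible(x)
}
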