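# Scenario sweeps over the core solver. Each study re-solves perturbed
# copies of a problem instance and records a tidy one-row-per-scenario
# summary, reproducible from (scenario id, seed, configuration).

scenario_record <- function(scenario_id, description, res) {
  data.frame(
    scenario_id = scenario_id,
    description = description,
    t_star = res$t_star,
    n_facilities = length(res$open_facilities),
    facility_ids = paste(res$open_facilities, collapse = ","),
    production_total = res$production_total,
    objective = res$objective,
    stringsAsFactors = FALSE
  )
}

scenario_na_record <- function(scenario_id, description) {
  data.frame(scenario_id = scenario_id, description = description,
             t_star = NA_real_, n_facilities = NA_integer_,
             facility_ids = NA_character_, production_total = NA_real_,
             objective = NA_real_, stringsAsFactors = FALSE)
}

#' Reef-subset sensitivity study
#'
#' Draws `n_subsets` seeded random subsets of `subset_size` reefs from a
#' reef field, solves each resulting instance, and tallies how often each
#' candidate facility appears in the optimal solution and how many
#' facilities optimal solutions open.
#'
#' @param all_reefs reef data.frame to subsample from.
#' @param n_subsets number of problem instances to generate.
#' @param subset_size reefs per instance, `<= nrow(all_reefs)`.
#' @param facilities candidate sites, default [default_ports()].
#' @param demand,cost,survival,config instance components (see
#'   [build_instance()]).
#' @param seed base seed; subset `k` uses `seed + k`.
#' @return a list with `frequency` (per-facility selection counts and
#'   proportions), `n_facility_counts` (table of optimal facility counts),
#'   and `records` (per-scenario data.frame).
#' @export
reef_subset_study <- function(all_reefs, n_subsets, subset_size,
                              facilities = default_ports(),
                              demand = demand_params(), cost = cost_params(),
                              survival = survival_spec(),
                              config = solver_config(), seed = 1) {
  stopifnot(subset_size <= nrow(all_reefs))
  records <- vector("list", n_subsets)
  open_sets <- vector("list", n_subsets)
  for (k in seq_len(n_subsets)) {
    reefs_k <- select_reef_subset(all_reefs, subset_size, seed = seed + k)
    res <- two_stage_solve(build_instance(reefs_k, facilities, demand,
                                          cost, survival, config))
    records[[k]] <- scenario_record(sprintf("subset_%03d", k),
                                    sprintf("seed %d", seed + k), res)
    open_sets[[k]] <- res$open_facilities
  }
  counts <- vapply(facilities$id,
                   function(f) sum(vapply(open_sets, function(s) f %in% s,
                                          logical(1))),
                   integer(1))
  list(
    frequency = data.frame(facility = facilities$id, count = counts,
                           proportion = counts / n_subsets),
    n_facility_counts = table(vapply(open_sets, length, integer(1))),
    records = do.call(rbind, records)
  )
}

# Return a copy of `instance` with one cost parameter scaled by `factor`.
# Scaling c_d_op rescales the trip-cost matrix (linear in c_d_op); the
# other parameters only enter the objective.
scale_cost_param <- function(instance, parameter, factor) {
  stopifnot(parameter %in% c("c_f_cap", "c_v_cap", "c_f_op", "c_d_op"))
  cp <- instance$cost_params
  cp[[parameter]] <- cp[[parameter]] * factor
  trip <- instance$trip_costs
  if (parameter == "c_d_op") trip <- trip * factor
  if (cp[[parameter]] > 0) {
    cp <- do.call(cost_params, cp)
  } else {
    # factor 0 (the 2^-inf scenario): bypass the positivity check
    cls <- class(cp)
    cp <- unclass(cp)
    class(cp) <- cls
  }
  problem_instance(instance$clusters, instance$facilities, cp,
                   instance$survival, instance$config, trip_costs = trip)
}

#' Cost-parameter scaling study
#'
#' Re-solves an instance with one cost parameter multiplied by `2^x` for
#' each exponent `x` (exponent `-Inf` maps to a zero parameter) and records
#' each scenario, flagging the smallest upward and downward exponents at
#' which the optimal facility set changes from the base case.
#'
#' @param instance a [problem_instance()] solvable at the base case.
#' @param parameter one of `"c_f_cap"`, `"c_v_cap"`, `"c_f_op"`, `"c_d_op"`.
#' @param exponents integer exponents (may include `-Inf`); 0 is the base
#'   case and is added if missing.
#' @return a data.frame of scenario records with columns `exponent` and
#'   `changed` (facility set differs from base) appended.
#' @export
cost_scaling_study <- function(instance, parameter,
                               exponents = c(-2, -1, 0, 1, 2)) {
  if (!0 %in% exponents) exponents <- c(0, exponents)
  exponents <- exponents[order(abs(exponents), exponents)]
  recs <- vector("list", length(exponents))
  base_fac <- NULL
  for (k in seq_along(exponents)) {
    x <- exponents[k]
    fac <- if (is.infinite(x) && x < 0) 0 else 2^x
    res <- two_stage_solve(scale_cost_param(instance, parameter, fac))
    recs[[k]] <- scenario_record(
      sprintf("%s_x%s", parameter, format(x)),
      sprintf("%s scaled by 2^%s", parameter, format(x)), res)
    recs[[k]]$exponent <- x
    if (x == 0) base_fac <- recs[[k]]$facility_ids
  }
  out <- do.call(rbind, recs)
  out$changed <- out$facility_ids != base_fac
  out
}

#' Maximum-survival sweep
#'
#' Re-solves an instance across a sequence of `pmax` values of its
#' (asymptotic) survival curve, recording cost, growth time, facilities and
#' production for each.
#'
#' @param instance a [problem_instance()] with an asymptotic survival spec.
#' @param pmax_values survival caps to assess (default 0.1 to 1 by 0.1).
#' @return a data.frame of scenario records with column `pmax` appended.
#' @export
pmax_sweep <- function(instance, pmax_values = seq(0.1, 1, by = 0.1)) {
  sp <- instance$survival
  if (sp$form != "asymptotic") {
    stop("pmax_sweep expects an asymptotic survival spec", call. = FALSE)
  }
  recs <- lapply(seq_along(pmax_values), function(k) {
    pm <- pmax_values[k]
    sp_k <- survival_spec("asymptotic", c = sp$c, t0 = sp$t0, pmax = pm,
                          pmin = min(sp$pmin, pm / 2), pmin_allow = sp$pmin_allow)
    inst_k <- problem_instance(instance$clusters, instance$facilities,
                               instance$cost_params, sp_k, instance$config,
                               trip_costs = instance$trip_costs)
    res <- two_stage_solve(inst_k)
    r <- scenario_record(sprintf("pmax_%03.0f", 100 * pm),
                         sprintf("pmax = %g", pm), res)
    r$pmax <- pm
    r
  })
  do.call(rbind, recs)
}

# Default per-form scaling-factor ranges for survival_form_grid.
default_c_range <- function(form) {
  switch(form,
         asymptotic   = c(5, 55),
         linear       = c(0.05, 0.5),
         logistic     = c(5, 55),
         pseudo_gamma = c(5, 30),
         stop("unknown form", call. = FALSE))
}

#' Survival-curve parameter grid study
#'
#' Re-solves an instance over a grid of survival-curve parameters
#' (scaling factor `c` by horizontal shift `t0`) for one functional form.
#' Grids on which every growth time is excluded are recorded as infeasible
#' cells rather than raising an error.
#'
#' @param instance a [problem_instance()].
#' @param form survival functional form.
#' @param c_values grid of scaling factors; default 11 increments over the
#'   form's standard range.
#' @param t0_values grid of horizontal shifts; default 11 increments over
#'   `[0, 0.5]`.
#' @return a data.frame of scenario records with columns `form`, `c`, `t0`
#'   appended (`NA` records mark infeasible cells).
#' @export
survival_form_grid <- function(instance, form = "asymptotic",
                               c_values = NULL, t0_values = NULL) {
  if (is.null(c_values)) {
    r <- default_c_range(form)
    c_values <- seq(r[1], r[2], length.out = 11)
  }
  if (is.null(t0_values)) t0_values <- seq(0, 0.5, length.out = 11)
  sp <- instance$survival
  grid <- expand.grid(c = c_values, t0 = t0_values)
  recs <- lapply(seq_len(nrow(grid)), function(k) {
    sp_k <- survival_spec(form, c = grid$c[k], t0 = grid$t0[k],
                          pmax = sp$pmax, pmin = sp$pmin,
                          pmin_allow = sp$pmin_allow)
    inst_k <- problem_instance(instance$clusters, instance$facilities,
                               instance$cost_params, sp_k, instance$config,
                               trip_costs = instance$trip_costs)
    id <- sprintf("%s_c%g_t0%g", form, grid$c[k], grid$t0[k])
    g <- survival_grid(sp_k, instance$config$t_min, instance$config$t_max,
                       instance$config$dt)
    r <- if (!any(g$included)) {
      scenario_na_record(id, "all growth times excluded")
    } else {
      scenario_record(id, sprintf("%s c=%g t0=%g", form, grid$c[k], grid$t0[k]),
                      two_stage_solve(inst_k))
    }
    r$form <- form; r$c <- grid$c[k]; r$t0 <- grid$t0[k]
    r
  })
  do.call(rbind, recs)
}
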