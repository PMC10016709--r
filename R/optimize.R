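#' Big-M production bound for facility linking
#'
#' The linking constraint `sum_i X_ij <= M * Y_j` needs `M` at least as
#' large as any production a single facility could carry. Following the
#' model definition, `M` is the total surviving-unit demand divided by the
#' minimum survival rate over the included growth-time grid (grid-global,
#' not per grid point).
#'
#' @param instance a [problem_instance()].
#' @return `M` in produced units/year (0 when total demand is 0).
#' @export
big_M <- function(instance) {
  stopifnot(inherits(instance, "problem_instance"))
  D <- sum(instance$clusters$annual_demand)
  if (D == 0) return(0)
  g <- survival_grid(instance$survival, instance$config$t_min,
                     instance$config$t_max, instance$config$dt)
  if (!any(g$included)) {
    stop("no growth time on the grid has survival above pmin_allow",
         call. = FALSE)
  }
  D / min(g$survival[g$included])
}

# Variable layout used by build_mip / decode_solution:
# X_ij at (j-1)*I + i, then T_ij offset I*J, then Y_j offset 2*I*J.
mip_layout <- function(I, J) {
  list(I = I, J = J, nX = I * J, nT = I * J, nY = J, n = 2 * I * J + J,
       offT = I * J, offY = 2 * I * J)
}

#' Build the inner MIP at a fixed growth time
#'
#' Constructs the linear mixed-integer model solved by the inner stage:
#' continuous production `X_ij >= 0`, integer trips `T_ij >= 0`, binary
#' opening decisions `Y_j`, with
#' \itemize{
#'   \item trips capacity: `X_ij <= s_c * T_ij` for each pair,
#'   \item deployment frequency: `t * sum_i T_ij >= Y_j` for each facility
#'     (the minimum number of deployment events applies to open facilities),
#'   \item demand survival: `sum_j X_ij >= d_i / P(t)` for each cluster,
#'   \item big-M linking: `sum_i X_ij <= M * Y_j` for each facility.
#' }
#' The objective is the annualized cost: amortized fixed capital per open
#' facility, trip costs, and the per-unit residence cost
#' `t * (CRF * c_v_cap * a + c_f_op)` on every produced unit.
#'
#' The formulation is tightened with reductions that provably preserve the
#' optimum: per-cluster aggregate trip cuts
#' `sum_j T_ij >= ceil(d_i / (P(t) s_c))` (implied by the capacity and
#' demand constraints plus integrality), variable bounds
#' `X_ij <= d_i / P(t)` and `T_ij <= ceil(d_i / (P(t) s_c)) + ceil(1/t)`
#' (some optimum always satisfies them, since excess production and excess
#' trips only add cost), and the cover cut `sum_j Y_j >= 1` when total
#' demand is positive. These strengthen the LP relaxation so branch and
#' bound proves optimality quickly despite the weak big-M linking.
#'
#' @param instance a [problem_instance()].
#' @param t_hat fixed growth time in years; its survival must exceed the
#'   spec's `pmin_allow` cutoff.
#' @return an internal `milp_model` ready for [solve_mip()].
#' @export
build_mip <- function(instance, t_hat) {
  stopifnot(inherits(instance, "problem_instance"))
  P <- evaluate_survival(instance$survival, t_hat)
  if (P <= instance$survival$pmin_allow) {
    stop(sprintf("growth time %g is excluded: survival %g <= pmin_allow %g",
                 t_hat, P, instance$survival$pmin_allow), call. = FALSE)
  }
  d <- instance$clusters$annual_demand
  cp <- instance$cost_params
  lay <- mip_layout(length(d), nrow(instance$facilities))
  I <- lay$I; J <- lay$J
  crf <- capital_recovery_factor(cp$interest, cp$horizon)
  u <- unit_production_cost(cp, t_hat)
  M <- big_M(instance)
  x_req <- d / P

  obj <- c(rep(u, lay$nX), as.numeric(instance$trip_costs),
           rep(crf * cp$c_f_cap, J))
  integer <- c(rep(FALSE, lay$nX), rep(TRUE, lay$nT), rep(TRUE, J))
  K <- ceil_tol(1 / t_hat)
  n_trips <- ceil_tol(x_req / cp$s_c)
  lb <- rep(0, lay$n)
  ub <- c(rep(x_req, times = J), rep(n_trips + K, times = J), rep(1, J))

  ai <- integer(0); aj <- integer(0); ax <- numeric(0)
  add <- function(i, j, x) {
    ai <<- c(ai, i); aj <<- c(aj, j); ax <<- c(ax, x)
  }
  pair <- seq_len(I * J)
  # rows 1..IJ: X_ij - s_c T_ij <= 0
  add(pair, pair, rep(1, I * J))
  add(pair, lay$offT + pair, rep(-cp$s_c, I * J))
  # rows IJ+1..IJ+J: t * sum_i T_ij - Y_j >= 0
  r2 <- I * J + rep(seq_len(J), each = I)
  add(r2, lay$offT + pair, rep(t_hat, I * J))
  add(I * J + seq_len(J), lay$offY + seq_len(J), rep(-1, J))
  # rows IJ+J+1..IJ+J+I: sum_j X_ij >= d_i / P
  r3 <- I * J + J + rep(seq_len(I), times = J)
  add(r3, pair, rep(1, I * J))
  # rows IJ+J+I+1..: sum_i X_ij - M Y_j <= 0
  r4 <- I * J + J + I + rep(seq_len(J), each = I)
  add(r4, pair, rep(1, I * J))
  add(I * J + J + I + seq_len(J), lay$offY + seq_len(J), rep(-M, J))
  # LP-tightening cuts (optimum-preserving, see Details):
  # rows ..+1..+I: sum_j T_ij >= ceil(x_i / s_c)
  r5 <- I * J + J + I + J + rep(seq_len(I), times = J)
  add(r5, lay$offT + pair, rep(1, I * J))
  # final row: sum_j Y_j >= 1 when there is demand
  r6 <- I * J + J + I + J + I + 1L
  add(rep(r6, J), lay$offY + seq_len(J), rep(1, J))

  ncon <- I * J + J + I + J + I + 1L
  clb <- c(rep(-Inf, I * J), rep(0, J), x_req, rep(-Inf, J),
           n_trips, if (sum(d) > 0) 1 else 0)
  cub <- c(rep(0, I * J), rep(Inf, J), rep(Inf, I), rep(0, J),
           rep(Inf, I), Inf)

  milp_model(obj, integer, lb, ub, ai, aj, ax, clb, cub, ncon = ncon,
             vars = list(layout = lay, t_hat = t_hat, survival = P,
                         x_req = x_req, M = M))
}

decode_mip_solution <- function(model, raw) {
  lay <- model$vars$layout
  if (raw$status != "optimal" || length(raw$x) != lay$n) {
    return(structure(list(X = NULL, Y = NULL, T = NULL,
                          objective = raw$objective, status = raw$status),
                     class = "mip_solution"))
  }
  X <- matrix(raw$x[seq_len(lay$nX)], lay$I, lay$J)
  Tm <- matrix(round(raw$x[lay$offT + seq_len(lay$nT)]), lay$I, lay$J)
  Y <- round(raw$x[lay$offY + seq_len(lay$nY)])
  X[X < 0] <- 0
  structure(list(X = X, Y = Y, T = Tm, objective = raw$objective,
                 status = raw$status, t = model$vars$t_hat,
                 survival = model$vars$survival),
            class = "mip_solution")
}

#' Solve one inner MIP
#'
#' Sends a [build_mip()] model to the MILP backend (HiGHS) and decodes the
#' result into production, trip and opening matrices.
#'
#' @param model a model from [build_mip()].
#' @param mip_gap relative optimality gap (default 0, proven optimality).
#' @param time_limit optional seconds limit.
#' @return a `mip_solution`: list with `X`, `Y`, `T`, `objective`,
#'   `status` (`"optimal"`, `"infeasible"` or `"limit"`).
#' @export
solve_mip <- function(model, mip_gap = 0, time_limit = NULL) {
  stopifnot(inherits(model, "milp_model"))
  raw <- milp_solve_batch(list(model), mip_gap = mip_gap,
                          time_limit = time_limit)[[1]]
  decode_mip_solution(model, raw)
}

#' Two-stage facility location, sizing and growth-time optimization
#'
#' Outer stage: enumerate the growth-time grid, skipping growth times whose
#' survival is at or below the `pmin_allow` cutoff. Inner stage: solve the
#' MIP of [build_mip()] at each included growth time (all grid points are
#' dispatched to the backend in a single batch). The incumbent is replaced
#' only on a strictly smaller objective, so the smallest growth time
#' attaining the minimum wins ties; `t*` is accurate to within half a grid
#' step of the continuous-time optimum.
#'
#' @param instance a [problem_instance()].
#' @return an object of class `reefplan_solution` with components
#'   `t_star`, `objective`, `solution` (the incumbent `mip_solution`),
#'   `breakdown` (see [annual_cost_breakdown()]), `production_total`,
#'   `open_facilities`, `trace` (per-grid-point data.frame) and `instance`.
#' @export
#' @examples
#' \dontrun{
#' reefs <- generate_synthetic_reefs(synthetic_field_spec(n_reefs = 50, seed = 7))
#' res <- two_stage_solve(build_instance(reefs))
#' summary(res)
#' }
two_stage_solve <- function(instance) {
  stopifnot(inherits(instance, "problem_instance"))
  cfg <- instance$config
  g <- survival_grid(instance$survival, cfg$t_min, cfg$t_max, cfg$dt)
  if (!any(g$included)) {
    stop("infeasible: every growth time on the grid is excluded by pmin_allow",
         call. = FALSE)
  }
  inc <- which(g$included)
  models <- lapply(g$t[inc], function(tt) build_mip(instance, tt))
  raws <- milp_solve_batch(models, mip_gap = cfg$mip_gap,
                           time_limit = cfg$time_limit)
  trace <- data.frame(t = g$t, survival = g$survival, included = g$included,
                      status = NA_character_, objective = NA_real_)
  sols <- vector("list", length(inc))
  for (k in seq_along(inc)) {
    sols[[k]] <- decode_mip_solution(models[[k]], raws[[k]])
    trace$status[inc[k]] <- sols[[k]]$status
    if (sols[[k]]$status == "optimal") {
      trace$objective[inc[k]] <- sols[[k]]$objective
    }
  }
  solved <- which(vapply(sols, function(s) s$status == "optimal", logical(1)))
  if (length(solved) == 0L) {
    stop("no growth time solved to optimality; inspect solver status",
         call. = FALSE)
  }
  objs <- vapply(sols[solved], `[[`, numeric(1), "objective")
  best <- solved[which.min(objs)] # first minimum: smallest t wins ties
  sol <- sols[[best]]
  bd <- annual_cost_breakdown(sol, sol$t, instance)
  structure(list(
    t_star = sol$t,
    objective = sol$objective,
    solution = sol,
    breakdown = bd,
    production_total = sum(sol$X),
    open_facilities = instance$facilities$id[sol$Y > 0.5],
    trace = trace,
    instance = instance
  ), class = "reefplan_solution")
}

# ---- exact oracle ----------------------------------------------------------

# Exact integer transportation subproblem: choose trips T_ij >= 0 minimizing
# sum(C * T) subject to row sums >= need_i (enough vessel capacity for each
# cluster's production) and column sums >= K (minimum deployment events per
# open facility). The constraint matrix is totally unimodular, but with no
# reliable LP solver available in R this is solved exactly by dynamic
# programming over columns: the state is the vector of still-uncovered row
# needs, and within a column the optimal top-up to K trips is analytic
# (empty trips go to the cheapest row). Loaded trips beyond a row's need are
# dominated by top-up trips in the column's cheapest row, so allocations
# a_i <= need_i are exhaustive.
transport_min_cost <- function(C, need, K) {
  I <- nrow(C); J <- ncol(C)
  stopifnot(length(need) == I, all(need >= 0), K >= 0)
  dims <- need + 1L
  nstates <- prod(dims)
  if (nstates > 1500) {
    stop("instance too large for the brute-force oracle", call. = FALSE)
  }
  S_mat <- as.matrix(expand.grid(lapply(dims, function(d) 0:(d - 1L))))
  mult <- cumprod(c(1L, utils::head(dims, -1L)))
  idx_of <- function(s) 1L + as.integer(s %*% mult)

  # all (prev, alloc) pairs with alloc <= prev elementwise
  cross_prev <- rep(seq_len(nstates), each = nstates)
  cross_a <- rep(seq_len(nstates), times = nstates)
  ok <- rowSums(S_mat[cross_a, , drop = FALSE] >
                  S_mat[cross_prev, , drop = FALSE]) == 0L
  ip <- cross_prev[ok]; ia <- cross_a[ok]
  ir <- 1L + as.integer((S_mat[ip, , drop = FALSE] -
                           S_mat[ia, , drop = FALSE]) %*% mult)

  h <- rep(Inf, nstates)
  h[idx_of(rep(0L, I))] <- 0 # after the last column no need may remain
  amin <- matrix(NA_integer_, nstates, J)
  for (j in rev(seq_len(J))) {
    costA <- as.numeric(S_mat %*% C[, j]) +
      pmax(0, K - rowSums(S_mat)) * min(C[, j])
    cand <- costA[ia] + h[ir]
    o <- order(cand)
    first <- !duplicated(ip[o])
    h_new <- rep(Inf, nstates)
    h_new[ip[o][first]] <- cand[o][first]
    amin[ip[o][first], j] <- ia[o][first]
    h <- h_new
  }
  start <- idx_of(need)
  if (!is.finite(h[start])) return(list(cost = Inf, T = NULL))

  Tm <- matrix(0L, I, J)
  s <- start
  for (j in seq_len(J)) {
    a_idx <- amin[s, j]
    a <- S_mat[a_idx, ]
    Tm[, j] <- as.integer(a)
    extra <- K - sum(a)
    if (extra > 0) {
      r <- which.min(C[, j])
      Tm[r, j] <- Tm[r, j] + as.integer(extra)
    }
    s <- idx_of(S_mat[s, ] - a)
  }
  list(cost = h[start], T = Tm)
}

#' Exhaustive-enumeration oracle for small instances
#'
#' Independent reference for the inner MIP at a fixed growth time, used to
#' verify the solver path. Enumerates every subset of facilities to open;
#' for each subset the remaining problem reduces to an exact integer
#' transportation problem over trips (production splits freely across open
#' facilities at a common unit cost, so only trips and opening costs vary),
#' solved by dynamic programming. Intended for instances with at most 6
#' clusters and 6 facilities and small trip counts.
#'
#' @param instance a [problem_instance()].
#' @param t_hat fixed growth time (years), not excluded by `pmin_allow`.
#' @return a `mip_solution` (as from [solve_mip()]) with the global optimum.
#' @export
brute_force_oracle <- function(instance, t_hat) {
  stopifnot(inherits(instance, "problem_instance"))
  d <- instance$clusters$annual_demand
  I <- length(d); J <- nrow(instance$facilities)
  if (I > 6 || J > 6) {
    stop("brute-force oracle is limited to |I| <= 6 and |J| <= 6", call. = FALSE)
  }
  P <- evaluate_survival(instance$survival, t_hat)
  if (P <= instance$survival$pmin_allow) {
    stop(sprintf("growth time %g is excluded by pmin_allow", t_hat),
         call. = FALSE)
  }
  cp <- instance$cost_params
  crf <- capital_recovery_factor(cp$interest, cp$horizon)
  u <- unit_production_cost(cp, t_hat)
  x_req <- d / P
  need <- ceil_tol(x_req / cp$s_c)
  K <- ceil_tol(1 / t_hat)
  prod_cost <- u * sum(x_req)

  best <- list(cost = Inf, S = integer(0), T = NULL)
  if (sum(d) == 0) best <- list(cost = 0, S = integer(0), T = matrix(0L, I, J))
  for (mask in seq_len(2^J - 1L)) {
    S <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(J) - 1L)) > 0L)
    tr <- transport_min_cost(instance$trip_costs[, S, drop = FALSE], need, K)
    if (!is.finite(tr$cost)) next
    total <- crf * cp$c_f_cap * length(S) + prod_cost + tr$cost
    if (total < best$cost) {
      Tm <- matrix(0L, I, J)
      Tm[, S] <- tr$T
      best <- list(cost = total, S = S, T = Tm)
    }
  }
  if (!is.finite(best$cost)) {
    stop("oracle found no feasible facility subset", call. = FALSE)
  }
  Y <- as.integer(seq_len(J) %in% best$S)
  # distribute each cluster's production over the trips that carry it
  X <- matrix(0, I, J)
  for (i in seq_len(I)) {
    rem <- x_req[i]
    for (j in best$S) {
      if (rem <= 0) break
      take <- min(rem, cp$s_c * best$T[i, j])
      X[i, j] <- take
      rem <- rem - take
    }
  }
  structure(list(X = X, Y = Y, T = best$T, objective = best$cost,
                 status = "optimal", t = t_hat, survival = P),
            class = "mip_solution")
}

#' Arithmetic feasibility check of a solution
#'
#' Re-checks every model constraint outside the solver: trip capacity,
#' deployment frequency, demand survival, big-M linking, and variable
#' domains. Used by the test-suite to validate solver output.
#'
#' @param instance a [problem_instance()].
#' @param sol a `mip_solution`.
#' @param tol absolute slack allowed on scaled constraints.
#' @return `TRUE` if feasible, otherwise a character vector of violations.
#' @export
check_solution <- function(instance, sol, tol = 1e-5) {
  d <- instance$clusters$annual_demand
  cp <- instance$cost_params
  P <- sol$survival
  viol <- character(0)
  scale <- max(1, sum(d) / max(P, 1e-12))
  if (any(sol$X < -tol * scale)) viol <- c(viol, "X >= 0")
  if (any(sol$T < 0) || any(abs(sol$T - round(sol$T)) > 1e-6)) {
    viol <- c(viol, "T integer >= 0")
  }
  if (any(!sol$Y %in% c(0, 1))) viol <- c(viol, "Y binary")
  if (any(sol$X - cp$s_c * sol$T > tol * scale)) {
    viol <- c(viol, "trip capacity X <= s_c T")
  }
  if (any(sol$t * colSums(sol$T) - sol$Y < -1e-6)) {
    viol <- c(viol, "deployment frequency t sum(T) >= Y")
  }
  if (any(P * rowSums(sol$X) - d < -tol * max(1, max(d)))) {
    viol <- c(viol, "demand survival P sum(X) >= d")
  }
  M <- big_M(instance)
  if (any(colSums(sol$X) - M * sol$Y > tol * scale)) {
    viol <- c(viol, "big-M linking sum(X) <= M Y")
  }
  if (length(viol) == 0L) TRUE else viol
}
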