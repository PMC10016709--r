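test_that("big-M is total demand over the minimum included survival", {
  inst <- make_small_instance(1, I = 2, J = 2)
  D <- sum(inst$clusters$annual_demand)
  # grid 0.25..1 step 0.25; asymptotic is increasing so the minimum is at t_min
  p_min <- evaluate_survival(inst$survival, 0.25)
  expect_equal(big_M(inst), D / p_min)

  inst0 <- inst
  inst0$clusters$annual_demand[] <- 0
  expect_equal(big_M(inst0), 0)

  # all growth times excluded: error
  inst_x <- make_small_instance(1, I = 2, J = 2)
  inst_x$survival <- survival_spec("linear", c = 0.2, t0 = 0.2)
  inst_x$config <- solver_config(t_min = 0.02, t_max = 0.18, dt = 0.02)
  expect_error(big_M(inst_x), "pmin_allow")
})

test_that("the inner model has the documented shape and guards", {
  inst <- make_small_instance(2, I = 1, J = 1)
  m <- build_mip(inst, 0.5)
  expect_equal(length(m$obj), 3) # X, T, Y
  expect_equal(m$integer, c(FALSE, TRUE, TRUE))
  expect_error(build_mip(inst, -1), ">= 0") # negative growth time
  inst$survival <- survival_spec("linear", c = 0.2, t0 = 0.2)
  expect_error(build_mip(inst, 0.1), "excluded")
})

test_that("inner MIP agrees with the enumeration oracle across seeds and grid", {
  models <- list(); oracle_obj <- numeric(0)
  insts <- lapply(1:25, make_small_instance)
  for (inst in insts) {
    g <- survival_grid(inst$survival, inst$config$t_min,
                       inst$config$t_max, inst$config$dt)
    for (tt in g$t[g$included]) {
      models[[length(models) + 1]] <- build_mip(inst, tt)
      oracle_obj <- c(oracle_obj, brute_force_oracle(inst, tt)$objective)
    }
  }
  raws <- reefplan:::milp_solve_batch(models)
  mip_obj <- vapply(raws, `[[`, numeric(1), "objective")
  expect_true(all(vapply(raws, `[[`, character(1), "status") == "optimal"))
  expect_equal(mip_obj, oracle_obj, tolerance = 1e-9)
})

test_that("solver output is arithmetically feasible and matches its breakdown", {
  for (seed in c(3, 17)) {
    inst <- make_small_instance(seed, I = 3, J = 3)
    res <- two_stage_solve(inst)
    expect_true(isTRUE(check_solution(inst, res$solution)))
    bd <- annual_cost_breakdown(res$solution, res$t_star, inst)
    expect_equal(bd$total, res$objective, tolerance = 1e-6)
    expect_true(all(unlist(bd) >= 0))
    # demand met with equality at the optimum (production is costly)
    met <- res$solution$survival * rowSums(res$solution$X)
    expect_equal(met, inst$clusters$annual_demand, tolerance = 1e-6)
  }
})

test_that("1x1 instance has the closed-form optimum", {
  inst <- make_small_instance(4, I = 1, J = 1)
  tt <- 0.5
  P <- evaluate_survival(inst$survival, tt)
  x <- inst$clusters$annual_demand / P
  cp <- inst$cost_params
  crf <- capital_recovery_factor(cp$interest, cp$horizon)
  trips <- max(ceiling(x / cp$s_c), ceiling(1 / tt))
  want <- crf * cp$c_f_cap + inst$trip_costs[1, 1] * trips +
    x * tt * (crf * cp$c_v_cap * cp$a + cp$c_f_op)
  expect_equal(solve_mip(build_mip(inst, tt))$objective, want, tolerance = 1e-9)
  expect_equal(brute_force_oracle(inst, tt)$objective, want, tolerance = 1e-12)
})

test_that("two-stage search keeps the first strict minimum over the grid", {
  # flat survival at pmax: production is constant, residence cost grows with
  # t, so the smallest growth time wins
  inst <- make_small_instance(5, I = 2, J = 2)
  inst$survival <- survival_spec("linear", c = 1000, t0 = 0, pmax = 0.5)
  res <- two_stage_solve(inst)
  expect_equal(res$t_star, inst$config$t_min)
  expect_equal(nrow(res$trace), 4)
  expect_true(all(res$trace$included))

  # zero demand: every growth time costs 0; the tie goes to the smallest t
  inst0 <- make_small_instance(6, I = 2, J = 2)
  inst0$clusters$annual_demand[] <- 0
  res0 <- two_stage_solve(inst0)
  expect_equal(res0$objective, 0)
  expect_equal(res0$t_star, inst0$config$t_min)
  expect_equal(length(res0$open_facilities), 0)
})

test_that("an all-excluded growth-time grid is an infeasibility error", {
  inst <- make_small_instance(7, I = 2, J = 2)
  inst$survival <- survival_spec("linear", c = 0.2, t0 = 0.2)
  inst$config <- solver_config(t_min = 0.02, t_max = 0.18, dt = 0.02)
  expect_error(two_stage_solve(inst), "excluded")
})

test_that("scaling all cost parameters scales the optimum and keeps the plan", {
  inst <- make_small_instance(8, I = 3, J = 2)
  res1 <- two_stage_solve(inst)
  k <- 3.7
  cp <- inst$cost_params
  inst2 <- problem_instance(inst$clusters, inst$facilities,
                            cost_params(c_f_cap = k * cp$c_f_cap,
                                        c_v_cap = k * cp$c_v_cap,
                                        c_f_op = k * cp$c_f_op,
                                        c_d_op = k * cp$c_d_op),
                            inst$survival, inst$config)
  res2 <- two_stage_solve(inst2)
  expect_equal(res2$objective, k * res1$objective, tolerance = 1e-6)
  expect_equal(res2$t_star, res1$t_star)
  expect_equal(res2$solution$Y, res1$solution$Y)
})

test_that("the oracle rejects oversized instances and excluded growth times", {
  inst <- make_small_instance(9, I = 2, J = 2)
  inst$survival <- survival_spec("linear", c = 0.2, t0 = 0.2)
  expect_error(brute_force_oracle(inst, 0.1), "excluded")
  big <- make_small_instance(10, I = 4, J = 4)
  big$facilities <- rbind(big$facilities, big$facilities)
  big$facilities$id <- sprintf("f%d", 1:8)
  big$trip_costs <- cbind(big$trip_costs, big$trip_costs)
  expect_error(brute_force_oracle(big, 0.5), "<= 6")
})
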