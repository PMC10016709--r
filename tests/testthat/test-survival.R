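test_that("asymptotic survival reproduces known values", {
  sp <- survival_spec("asymptotic", c = 25, t0 = 0, pmax = 0.1)
  expect_equal(evaluate_survival(sp, 0.10), 0.02)
  expect_equal(evaluate_survival(sp, 0.02), 0.1 - 1 / (25 * 0.02 + 10))
  # x-intercept forced by the form: P(t0) = pmax - 1/(1/pmax) = 0
  for (pm in c(0.1, 0.5, 1)) {
    sp2 <- survival_spec("asymptotic", c = 7, t0 = 0.3, pmax = pm)
    expect_equal(evaluate_survival(sp2, 0.3), 0)
  }
  sp3 <- survival_spec("asymptotic", c = 25, t0 = 0, pmax = 0.5)
  expect_equal(evaluate_survival(sp3, 0.06), 0.5 - 1 / (25 * 0.06 + 2))
})

test_that("logistic midpoint and pseudo-gamma peak behave as the forms dictate", {
  sp <- survival_spec("logistic", c = 15, t0 = 0.2, pmax = 0.1)
  expect_equal(evaluate_survival(sp, 0.2), 0.05)
  # peak of x e^-x at x = 1, i.e. t = t0 + 1/c, value e^-1 before truncation
  sp_hi <- survival_spec("pseudo_gamma", c = 10, t0 = 0.2, pmax = 1)
  expect_equal(evaluate_survival(sp_hi, 0.3), exp(-1))
  sp_lo <- survival_spec("pseudo_gamma", c = 10, t0 = 0.2, pmax = 0.1)
  expect_equal(evaluate_survival(sp_lo, 0.3), 0.1) # truncated at pmax
})

test_that("truncation keeps every form within [0, pmax]", {
  set.seed(11)
  t_grid <- seq(0, 2, by = 0.05)
  for (form in c("asymptotic", "linear", "logistic", "pseudo_gamma")) {
    for (rep in 1:20) {
      sp <- survival_spec(form, c = runif(1, 0.1, 55), t0 = runif(1, 0, 0.5),
                          pmax = runif(1, 0.05, 1))
      p <- evaluate_survival(sp, t_grid)
      expect_true(all(p >= 0 & p <= sp$pmax + 1e-12),
                  label = sprintf("%s rep %d in bounds", form, rep))
    }
  }
})

test_that("monotone forms are non-decreasing and pseudo-gamma is unimodal", {
  set.seed(12)
  t_grid <- seq(0, 2, by = 0.01)
  for (rep in 1:10) {
    cc <- runif(1, 1, 40); t0 <- runif(1, 0, 0.5); pm <- runif(1, 0.1, 1)
    for (form in c("asymptotic", "logistic", "linear")) {
      p <- evaluate_survival(survival_spec(form, c = cc, t0 = t0, pmax = pm),
                             t_grid)
      expect_true(all(diff(p) >= -1e-12), label = paste(form, "non-decreasing"))
    }
    p <- evaluate_survival(
      survival_spec("pseudo_gamma", c = cc, t0 = t0, pmax = 1), t_grid)
    peak <- which.max(p)
    expect_true(all(diff(p[seq_len(peak)]) >= -1e-12))
    expect_true(all(diff(p[peak:length(p)]) <= 1e-12))
    expect_lt(abs(t_grid[peak] - (t0 + 1 / cc)), 0.011) # grid resolution
  }
})

test_that("asymptotic survival is pointwise non-decreasing in pmax beyond t0", {
  t_grid <- seq(0.21, 1.5, by = 0.01)
  pmaxes <- seq(0.1, 1, by = 0.1)
  vals <- sapply(pmaxes, function(pm) {
    evaluate_survival(survival_spec("asymptotic", c = 25, t0 = 0.2, pmax = pm),
                      t_grid)
  })
  expect_true(all(apply(vals, 1, function(r) all(diff(r) >= -1e-12))))
})

test_that("survival grid enumerates, truncates and flags exclusions", {
  base <- survival_spec("asymptotic", c = 25, t0 = 0, pmax = 0.1)
  g <- survival_grid(base, 0.02, 1.0, 0.02)
  expect_equal(nrow(g), 50)
  expect_equal(g$t[1], 0.02)
  expect_equal(g$t[50], 1.0)
  expect_true(all(g$included)) # P(0.02) = 0.0047619 > 1e-4
  expect_equal(min(g$survival), 0.1 - 1 / (25 * 0.02 + 10))

  lin <- survival_spec("linear", c = 0.2, t0 = 0.2)
  g2 <- survival_grid(lin, 0.02, 0.2, 0.02)
  expect_true(all(g2$survival == 0))
  expect_false(any(g2$included))

  g3 <- survival_grid(base, 0.1, 0.15, 0.2) # step larger than the range
  expect_equal(g3$t, 0.1)

  expect_error(survival_grid(base, 0.5, 0.1, 0.02), "t_min <= t_max")
  expect_error(survival_grid(base, 0.1, 0.5, -1), "dt")
})

test_that("required production inverts survival exactly", {
  expect_equal(required_production(7.124e6, 0.02), 356.2e6)
  expect_equal(required_production(0, 0.3), 0)
  set.seed(13)
  for (rep in 1:25) {
    D <- runif(1, 0, 1e8); P <- runif(1, 1e-4, 1)
    expect_equal(required_production(D, P) * P, D)
  }
  expect_error(required_production(1e6, 0), "survival")
  expect_error(required_production(-1, 0.5), "total_demand")
})

test_that("invalid survival specifications are rejected", {
  expect_error(survival_spec("asymptotic", c = -1), "'c'")
  expect_error(survival_spec("asymptotic", pmax = 1.2), "pmax")
  expect_error(survival_spec("asymptotic", pmin = 0.2, pmax = 0.1), "pmin")
  expect_error(survival_spec("gompertz"), "arg")
  sp <- survival_spec()
  expect_error(evaluate_survival(sp, NaN), "finite")
  expect_error(evaluate_survival(sp, -0.1), ">= 0")
})
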