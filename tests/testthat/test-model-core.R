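test_that("default time grid spans -140..90 at 1-min steps with 231 points", {
  g <- time_grid()
  expect_equal(g$n, 231)
  expect_equal(g$times[1], -140)
  expect_equal(g$times[g$n], 90)
  expect_equal(g$n, length(seq(g$t_start, g$t_end, by = g$dt)))
  expect_error(time_grid(dt = 0), "positive")
  expect_error(time_grid(t_start = 10), "straddle")
})

test_that("parameter domain is enforced", {
  expect_error(model_params(0, 9.3, 0.065, 0.12), "positive")
  expect_error(model_params(18, -1, 0.065, 0.12), "positive")
  expect_error(model_params(18, 9.3, -0.1, 0.12), "non-negative")
  expect_silent(model_params(18, 9.3, 0, 0))
})

test_that("licensing times follow the exponential construction", {
  set.seed(42)
  p <- model_params(18.0, 9.3, 0.065, 0.12)
  n <- 1e5
  lic <- replicate(n, unlist(draw_licensing_times(p)))
  t1 <- lic[1, ]; t2 <- lic[2, ]
  expect_true(all(t1 <= 0))
  expect_true(all(t2 >= t1))
  # median of the pre-NEBD licensing lag is tau1 * ln 2 = 12.5 min
  expect_equal(median(-t1), 18.0 * log(2), tolerance = 0.03)
  # mean of the licensing-2 delay equals its exponential scale
  expect_equal(mean(t2 - t1), 9.3, tolerance = 0.02)
  # degenerate scale: both licensing times collapse to ~0
  tiny <- draw_licensing_times(model_params(1e-9, 1e-9, 0, 0),
                               u = c(0.5, 0.5))
  expect_equal(tiny$t_lic1, 0, tolerance = 1e-6)
  expect_equal(tiny$t_lic2, 0, tolerance = 1e-6)
})

test_that("single-cell rules: zero rate, forced transitions, effect timing", {
  g <- time_grid()
  set.seed(1)
  s0 <- simulate_cell(model_params(18, 9.3, 0, 1), g)
  expect_true(all(s0 == "nonresolved"))

  # forced transitions (p ~ 1) with stubbed licensing times
  lic <- list(t_lic1 = -20, t_lic2 = -15)
  s <- simulate_cell(model_params(18, 9.3, 1e6, 1e6), g,
                     licensing = lic, u_steps = rep(0.5, g$n))
  expect_true(all(s[g$times < -20] == "nonresolved"))
  expect_equal(as.character(s[g$times == -20]), "nonresolved") # draw step
  expect_true(all(s[g$times > -20 & g$times <= -15] == "resolved"))
  expect_true(all(s[g$times > -15] == "compacted"))

  # effect-at-current-step variant shifts both transitions one step earlier
  s2 <- simulate_cell(model_params(18, 9.3, 1e6, 1e6), g,
                      effect = "current",
                      licensing = lic, u_steps = rep(0.5, g$n))
  expect_equal(as.character(s2[g$times == -20]), "resolved")
  expect_equal(as.character(s2[g$times == -15]), "compacted")
})

test_that("state sequences are monotone nonresolved* resolved* compacted*", {
  g <- time_grid()
  set.seed(7)
  for (i in 1:25) {
    p <- model_params(runif(1, 1, 40), runif(1, 1, 20),
                      runif(1, 0, 0.3), runif(1, 0, 0.3))
    s <- as.integer(simulate_cell(p, g))
    expect_true(all(diff(s) >= 0))
  }
})

test_that("population proportions partition the cohort and are reproducible", {
  p <- model_params(18, 9.3, 0.065, 0.12)
  pp <- simulate_population(p, m = 2000, seed = 3)
  expect_equal(pp$p_nonresolved + pp$p_resolved + pp$p_compacted,
               rep(1, nrow(pp)))
  pp2 <- simulate_population(p, m = 2000, seed = 3)
  expect_identical(pp, pp2)
  pp3 <- simulate_population(p, m = 2000, seed = 4)
  expect_false(identical(pp$p_nonresolved, pp3$p_nonresolved))
  # no compaction when r2 = 0
  pp0 <- simulate_population(model_params(18, 9.3, 0.065, 0), m = 500,
                             seed = 1)
  expect_true(all(pp0$p_compacted == 0))
  expect_error(simulate_population(p, m = 0), "m must be")
})

test_that("vectorised population path matches the per-cell reference exactly", {
  g <- time_grid()
  p <- model_params(15, 8, 0.08, 0.15)
  m <- 200
  draws <- sim_draws(m, g$n, seed = 9)
  pp <- chromkin:::sim_proportions(p, g, draws)
  counts <- matrix(0, g$n, 3)
  for (i in seq_len(m)) {
    lic <- list(t_lic1 = -qexp(draws$u_lic1[i], 1 / p$tau1),
                t_lic2 = NULL)
    lic$t_lic2 <- lic$t_lic1 + qexp(draws$u_lic2[i], 1 / p$tau2)
    s <- simulate_cell(p, g, licensing = lic, u_steps = draws$U[, i])
    counts <- counts + outer(as.integer(s), 1:3, "==")
  }
  expect_equal(pp$p_nonresolved, counts[, 1] / m)
  expect_equal(pp$p_resolved, counts[, 2] / m)
  expect_equal(pp$p_compacted, counts[, 3] / m)
})

test_that("Monte Carlo occupancy matches the closed-form licensing integral", {
  g <- time_grid()
  tau1 <- 18.0; r1 <- 0.065
  m <- 50000
  pp <- simulate_population(model_params(tau1, 9.3, r1, 0), g, m = m,
                            seed = 1)
  truth <- analytic_nonresolved(tau1, r1, g)
  se <- sqrt(truth * (1 - truth) / m)
  z <- (pp$p_nonresolved - truth) / pmax(se, 1e-12)
  expect_lt(max(abs(z)), 3.5)
})

test_that("instant licensing and infinite rate saturate resolution", {
  g <- time_grid()
  pp <- simulate_population(model_params(1e-9, 1e9, 1e9, 0), g, m = 200,
                            seed = 5)
  # one-step effect lag: resolved from the first grid point after NEBD
  expect_true(all(pp$p_nonresolved[g$times > 0] == 0))
  expect_true(all(pp$p_nonresolved[g$times < 0] == 1))
})

test_that("derived quantities reproduce the standard conversions", {
  dq <- derived_quantities(model_params(18.0, 9.3, 0.065, 0.12), dt = 1)
  expect_equal(round(dq$ST, 1), 12.5)
  # 9.3 * ln2 = 6.446, i.e. 6.4-6.5 min depending on rounding
  expect_equal(dq$TD, 9.3 * log(2))
  expect_lt(abs(dq$TD - 6.5), 0.06)
  expect_equal(round(dq$r1_half_life, 1), 10.7)
  expect_equal(round(dq$p1_step, 3), 0.063)
  dq0 <- derived_quantities(model_params(5, 5, 0, 0))
  expect_equal(dq0$p1_step, 0)
  expect_identical(dq0$r1_half_life, Inf)
})
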