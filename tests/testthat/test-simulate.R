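test_that("occupancy stays on the probability simplex", {
  for (pr in list(make_pulse(0.1, 0.01, post = 0.05),
                  make_train(0.001, 200, 20, 0.01))) {
    tr <- simulate_protocol(wt_tarp, pr)
    expect_lt(max(abs(rowSums(tr$occupancy) - 1)), 1e-8)
    expect_gt(min(tr$occupancy), -1e-12)
    expect_true(all(tr$current >= 0))
    expect_true(all(tr$current <= max(wt_tarp$states$conductance)))
  }
})

test_that("equilibrium initial conditions are stationary without agonist", {
  pr <- concentration_protocol(
    data.frame(duration = 0.3, concentration = 0))
  tr <- simulate_protocol(wt_tarp, pr)
  expect_lt(max(abs(tr$current - tr$current[1])), 1e-10)
  expect_lt(max(abs(sweep(tr$occupancy, 2, tr$occupancy[1, ]))), 1e-9)
})

test_that("matrix-exponential propagation matches an adaptive ODE oracle", {
  for (case in list(list(wt_notarp, make_pulse(0.2, 0.01, post = 0.05)),
                    list(wt_tarp, make_two_pulse(0.2, 0.1, 0.01, 0.01,
                                                 post = 0.02)))) {
    det <- simulate_protocol(case[[1]], case[[2]])
    ode <- ode_oracle(case[[1]], case[[2]])
    expect_lt(max(abs(det$occupancy - ode)), 1e-6)
  }
})

test_that("reported scalars are invariant to time-grid refinement", {
  coarse <- simulate_protocol(wt_tarp, make_pulse(0.2, 0.01, post = 0.05))
  fine <- simulate_protocol(wt_tarp, make_pulse(0.2, 0.01, post = 0.05,
                                                dt = 2.5e-5))
  pc <- peak_and_steady(coarse); pf <- peak_and_steady(fine)
  expect_lt(abs(pc$peak - pf$peak) / pf$peak, 0.001)
  expect_lt(abs(pc$steady - pf$steady) / pf$steady, 0.001)
})

test_that("unbalanced schemes are flagged before simulation", {
  raw <- build_scheme("TARP")
  expect_warning(simulate_protocol(raw, make_pulse(0.01, 0.01)),
                 "not balanced")
  expect_error(simulate_protocol(raw, make_pulse(0.01, 0.01),
                                 on_unbalanced = "error"),
               "not balanced")
  expect_error(simulate_protocol(wt_tarp, make_pulse(0.01, 0.01),
                                 initial = rep(1, 12)),
               "probability vector")
})

test_that("peak and steady-state measures behave on degenerate traces", {
  pr <- make_pulse(0.1, 0.01)
  flat <- list(time = seq(0, 1, 1e-3), current = rep(0.5, 1001),
               protocol = concentration_protocol(
                 data.frame(duration = 1, concentration = 0.01)))
  ps <- peak_and_steady(flat)
  expect_equal(ps$ratio_pct, 100)
  decay <- list(time = seq(0, 1, 1e-3),
                current = exp(-5 * seq(0, 1, 1e-3)),
                protocol = concentration_protocol(
                  data.frame(duration = 1, concentration = 0.01)))
  pd <- peak_and_steady(decay)
  expect_equal(pd$peak, 1)
  expect_lt(pd$steady, 0.01)
  expect_error(peak_and_steady(flat, window = c(2, 3)), "empty")
})

test_that("single-channel records occupy exactly one state at a time", {
  pr <- make_pulse(0.005, 0.01, pre = 0.002, post = 0.005, dt = 2e-4)
  st <- stochastic_simulate(wt_notarp, pr, n_channels = 1, seed = 3)
  expect_true(all(rowSums(st$occupancy) == 1))
  expect_true(all(st$occupancy %in% c(0, 1)))
})

test_that("stochastic simulation is reproducible given the seed", {
  pr <- make_pulse(0.005, 0.01, pre = 0.002, post = 0.005, dt = 2e-4)
  a <- stochastic_simulate(wt_notarp, pr, n_channels = 40, seed = 11)
  b <- stochastic_simulate(wt_notarp, pr, n_channels = 40, seed = 11)
  expect_identical(a$occupancy, b$occupancy)
  c2 <- stochastic_simulate(wt_notarp, pr, n_channels = 40, seed = 12)
  expect_false(identical(a$occupancy, c2$occupancy))
})

test_that("ensemble means converge to the master-equation solution", {
  pr <- make_pulse(0.008, 0.01, pre = 0.002, post = 0.01, dt = 2e-4)
  n <- 1500
  st <- stochastic_simulate(wt_notarp, pr, n_channels = n, seed = 11)
  det <- simulate_protocol(wt_notarp, pr)
  se <- sqrt(det$occupancy * (1 - det$occupancy) / n)
  # binomial sampling: practically no cell should sit beyond 4 SE, and
  # only the expected tail fraction beyond 3 SE
  dev <- abs(st$occupancy - det$occupancy)
  expect_lt(mean(dev > 3 * se + 1e-3), 0.01)
  expect_lt(max(abs(st$current - det$current)), 0.03)
})
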