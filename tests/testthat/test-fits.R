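test_that("multi-exponential fits recover their own model class", {
  t <- seq(0, 0.1, 5e-5)
  y <- 0.7 * exp(-100 * t) + 0.3 * exp(-10 * t)
  f <- fit_exponentials(t, y, n_components = 2)
  expect_equal(f$rates, c(100, 10), tolerance = 1e-3)
  expect_equal(f$amplitudes, c(0.7, 0.3), tolerance = 1e-3)
  expect_equal(f$weighted_rate, 0.7 * 100 + 0.3 * 10, tolerance = 1e-3)
  expect_equal(f$baseline, 0, tolerance = 1e-6)

  # single component: weighted rate equals that component's rate
  f1 <- fit_exponentials(t, 0.5 * exp(-40 * t) + 0.02, n_components = 1)
  expect_equal(f1$weighted_rate, f1$rates)
  expect_equal(f1$rates, 40, tolerance = 1e-3)
  expect_equal(f1$baseline, 0.02, tolerance = 1e-5)

  # rising relaxations (negative amplitude towards a baseline)
  fr <- fit_exponentials(t, 0.8 - 0.5 * exp(-30 * t), n_components = 1)
  expect_equal(fr$rates, 30, tolerance = 1e-3)
  expect_lt(fr$amplitudes, 0)
})

test_that("fits are deterministic and validate their inputs", {
  t <- seq(0, 0.05, 5e-5)
  y <- exp(-200 * t) + 0.2 * exp(-20 * t)
  f1 <- fit_exponentials(t, y, n_components = 2)
  f2 <- fit_exponentials(t, y, n_components = 2)
  expect_identical(f1$rates, f2$rates)
  expect_identical(f1$amplitudes, f2$amplitudes)
  expect_error(fit_exponentials(t[1:15], y[1:15], n_components = 2),
               "at least")
})

test_that("recovery fits invert their generating function", {
  iv <- c(0.005, 0.01, 0.02, 0.05, 0.1, 0.2, 0.35, 0.6)
  for (m in c(1, 2)) {
    resp <- 0.15 + 0.85 * (1 - exp(-22 * iv))^m
    f <- fit_recovery(iv, resp, exponent = m)
    expect_equal(f$k_rec, 22, tolerance = 1e-4)
    expect_equal(f$N0, 0.15, tolerance = 1e-4)
    expect_false(f$overshoot)
  }
  expect_error(fit_recovery(iv[1:3], rep(0.5, 3)), "at least 4")
  expect_error(fit_recovery(iv, rep(1, length(iv))), "unidentifiable")
})

test_that("suprarecovery fits recover overshooting curves exactly", {
  iv <- c(0.01, 0.025, 0.05, 0.1, 0.2, 0.35, 0.6, 1, 1.6, 2.5)
  truth <- list(n0 = 0.2, nsup = 0.15, ksup = 2, krec = 50)
  resp <- 1 + truth$nsup * exp(-truth$ksup * iv) -
    (1 - truth$n0 + truth$nsup) * exp(-truth$krec * iv)
  f <- fit_suprarecovery(iv, resp)
  expect_equal(f$model, "biexponential")
  expect_equal(f$k_rec, 50, tolerance = 1e-3)
  expect_equal(f$k_sup, 2, tolerance = 1e-3)
  expect_equal(f$N_sup, 0.15, tolerance = 1e-3)
  expect_equal(f$N0, 0.2, tolerance = 1e-3)
})

test_that("suprarecovery reduces to plain recovery as N_sup vanishes", {
  iv <- c(0.01, 0.025, 0.05, 0.1, 0.2, 0.35, 0.6, 1, 1.6, 2.5)
  resp <- 1 + 0.004 * exp(-2 * iv) - (1 - 0.2 + 0.004) * exp(-30 * iv)
  plain <- fit_recovery(iv, pmin(resp, 1))
  supra <- fit_suprarecovery(iv, resp)
  expect_lt(abs(plain$k_rec - supra$k_rec) / plain$k_rec, 0.05)
  # without any overshoot the suprarecovery fit falls back and says so
  fb <- fit_suprarecovery(iv, 0.2 + 0.8 * (1 - exp(-30 * iv)))
  expect_true(fb$fallback)
  expect_equal(fb$model, "HH")
})

test_that("Hill fits recover exact dose-response parameters", {
  conc <- 10^seq(-6, -2, length.out = 9)
  resp <- 0.8 * conc^1.3 / (conc^1.3 + (3e-4)^1.3)
  f <- fit_hill(conc, resp)
  expect_equal(f$ec50, 3e-4, tolerance = 1e-4)
  expect_equal(f$hill, 1.3, tolerance = 1e-4)
  expect_equal(f$ymax, 0.8, tolerance = 1e-4)
  expect_error(fit_hill(conc, rep(0.5, 9)), "unidentifiable")
  expect_error(fit_hill(conc[1:4], resp[1:4]), "at least 5")
})
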