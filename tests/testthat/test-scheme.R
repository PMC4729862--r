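test_that("the default rate set matches the published constants", {
  r <- default_rates()
  expect_equal(
    r[c("s*+", "s*-", "s+", "s-", "beta", "alpha", "beta_s",
        "d2*+", "d2*-", "d2+", "d2-", "d1+", "d1-", "d0+", "d0-",
        "k+", "k-", "kd-")],
    c(`s*+` = 15, `s*-` = 3, `s+` = 0.07, `s-` = 1, beta = 8000,
      alpha = 3000, beta_s = 5e5, `d2*+` = 120, `d2*-` = 2,
      `d2+` = 120, `d2-` = 5, `d1+` = 300, `d1-` = 25, `d0+` = 1,
      `d0-` = 3, `k+` = 5e6, `k-` = 4e4, `kd-` = 2500))
  k <- kainate_rates()
  expect_equal(unname(k[c("beta", "alpha", "d2+", "d2-", "d2*-",
                          "d1-", "beta_s")]),
               c(1600, 30000, 12, 30, 12, 300, 1e5))
})

test_that("the mutant trial table matches the published series", {
  tab <- mutant_trials()
  expect_equal(tab$trial, 0:8)
  expect_equal(tab$d2_minus,
               c(0.16, 0.32, 0.63, 1.26, 2.51, 5.0, 10.0, 19.9, 39.7))
  expect_equal(tab$d2star_minus,
               c(0.18, 0.29, 0.47, 0.76, 1.23, 2.0, 3.24, 5.26, 8.53))
  # per-trial shutting rate: anchored at the baseline for the wild-type
  # proxy, monotone along the series
  expect_equal(tab$alpha[tab$trial == 7], 3000)
  expect_true(all(diff(tab$alpha) > 0))
})

test_that("mutant trials substitute rates and clear the balanced flag", {
  sch <- apply_mutant_trial(build_scheme("TARP"), 7)
  expect_equal(sch$rates[["d2-"]], 19.9)
  expect_equal(sch$rates[["d2*-"]], 5.26)
  expect_equal(sch$rates[["alpha"]], 3000)
  expect_equal(sch$rates[["alpha_s"]], 3000)
  expect_false(sch$balanced)

  sch0 <- apply_mutant_trial(build_scheme("TARP"), 0)
  expect_equal(sch0$rates[["d2-"]], 0.16)
  expect_equal(sch0$rates[["d2*-"]], 0.18)
  # trial-varied basal shutting leaves the TARP-active layer untouched
  expect_lt(sch0$rates[["alpha"]], 3000)
  expect_equal(sch0$rates[["alpha_s"]], 3000)

  twice <- apply_mutant_trial(apply_mutant_trial(build_scheme("TARP"), 7), 7)
  expect_identical(twice$rates, apply_mutant_trial(build_scheme("TARP"), 7)$rates)

  expect_error(apply_mutant_trial(build_scheme("TARP"), 9), "0..8")
})

test_that("scheme construction produces the expected topologies", {
  nt <- build_scheme("noTARP")
  expect_equal(nrow(nt$states), 6)
  expect_equal(sum(nt$states$conductance > 0), 1)
  expect_equal(nt$states$conductance[nt$states$name == "AR*"], 0.4)

  wt <- build_scheme("TARP")
  expect_equal(nrow(wt$states), 2 * nrow(nt$states))
  open <- wt$states[wt$states$conductance > 0, ]
  expect_equal(nrow(open), 2)
  expect_equal(max(open$conductance) / min(open$conductance), 2.5)

  ctz <- build_scheme("TARP+CTZ")
  expect_equal(unname(ctz$rates[c("d0+", "d1+", "d2*+")]),
               c(0.1, 0.1, 0.1))
  expect_equal(ctz$rates[["d2+"]], 120)  # published list leaves d2+
  ctz2 <- build_scheme("TARP+CTZ", ctz_d2 = TRUE)
  expect_equal(ctz2$rates[["d2+"]], 0.1)

  ka <- build_scheme("kainate")
  expect_equal(min(ka$states$conductance[ka$states$conductance > 0]),
               0.08)
  expect_equal(max(ka$states$conductance), 1.0)

  ae <- build_scheme("alt-equal-conductance")
  g <- ae$states$conductance[ae$states$conductance > 0]
  expect_equal(unname(g), c(0.4, 0.4))

  expect_error(build_scheme("TARP", rates = default_rates()[-1]),
               "missing rate")
  bad <- default_rates(); bad[["beta"]] <- -1
  expect_error(build_scheme("TARP", rates = bad), "strictly positive")
  expect_error(build_scheme("nonsense"))
})

test_that("generator matrices conserve probability and scale binding", {
  for (v in c("noTARP", "TARP", "kainate", "alt-binding")) {
    sch <- build_scheme(v)
    for (conc in c(0, 1e-5, 0.01)) {
      Q <- generator_matrix(sch, conc)
      # conservation to machine precision relative to the rate scale
      expect_lt(max(abs(rowSums(Q))), 1e-12 * max(1, max(abs(Q))))
      expect_true(all(Q[row(Q) != col(Q)] >= 0))
    }
  }
  nt <- build_scheme("noTARP")
  expect_equal(generator_matrix(nt, 0.01)["R", "AR"], 5e6 * 0.01)
  Q0 <- generator_matrix(nt, 0)
  expect_equal(Q0["R", "AR"], 0)
  expect_equal(Q0["R", "AD1"], 0)   # re-binding into AD1 also off
  expect_error(generator_matrix(nt, -1), "non-negative")
})

test_that("equilibrium occupancy is a detailed-balance distribution", {
  p <- equilibrium_occupancy(wt_tarp, 0.01)
  expect_equal(sum(p), 1, tolerance = 1e-10)
  expect_true(all(p >= 0))
  # detailed balance on every transition of the balanced scheme
  Q <- generator_matrix(wt_tarp, 0.01)
  tr <- wt_tarp$transitions
  for (i in seq_len(nrow(tr))) {
    flux_fwd <- p[tr$from[i]] * Q[tr$from[i], tr$to[i]]
    flux_bwd <- p[tr$to[i]] * Q[tr$to[i], tr$from[i]]
    expect_equal(unname(flux_fwd), unname(flux_bwd), tolerance = 1e-8)
  }
})

test_that("at zero agonist only unliganded states are occupied", {
  p <- equilibrium_occupancy(wt_notarp, 0)
  expect_equal(unname(p[["R"]]), 1, tolerance = 1e-9)
  pw <- equilibrium_occupancy(wt_tarp, 0)
  expect_equal(sum(pw[c("Rs", "RS")]), 1, tolerance = 1e-9)
})

test_that("a few percent of complexes are basally superactive", {
  pw <- equilibrium_occupancy(wt_tarp, 0)
  # closed form: TARP activation equilibrium on the resting pair,
  # s+/s- / (1 + s+/s-)
  expect_equal(unname(pw[["RS"]]), 0.07 / 1.07, tolerance = 1e-9)
  expect_gt(pw[["RS"]], 0.03)
  expect_lt(pw[["RS"]], 0.07)
})

test_that("equilibrium open probability rises across the mutant series", {
  popen <- vapply(c(0L, 2L, 4L, 6L, 8L), function(tr) {
    sch <- build_trial_scheme("TARP", tr)
    p <- equilibrium_occupancy(sch, 0.01)
    sum(p[sch$states$conductance > 0])
  }, numeric(1))
  expect_true(all(diff(popen) > 0))
})
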