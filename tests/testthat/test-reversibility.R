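test_that("the printed rate set violates the cycle criterion as expected", {
  imb <- cycle_imbalance(build_scheme("TARP"))
  expect_gt(nrow(imb), 0)
  # open-pair cycle: product ratio 120,000 / 105,000 = 8/7 (orientation
  # may invert it)
  open_cycle <- grepl("ARs\\*", imb$cycle) & grepl("ARS\\*", imb$cycle)
  r <- imb$ratio[open_cycle]
  expect_length(r, 1)
  expect_true(isTRUE(all.equal(r, 8 / 7)) || isTRUE(all.equal(r, 7 / 8)))
})

test_that("balancing closes every cycle to 1e-10 in all variants", {
  for (v in scheme_variants()) {
    sch <- enforce_microscopic_reversibility(build_scheme(v))
    expect_true(sch$balanced)
    imb <- cycle_imbalance(sch)
    if (nrow(imb)) expect_lt(max(abs(imb$ratio - 1)), 1e-10)
  }
})

test_that("balanced dependent rates match their closed forms", {
  b <- enforce_microscopic_reversibility(build_scheme("TARP"))
  r <- default_rates()
  # open cycle: s*+ = s+ beta_s s*- / (beta s-)
  expect_equal(b$rates[["s*+"]],
               r[["s+"]] * r[["beta_s"]] * r[["s*-"]] /
                 (r[["beta"]] * r[["s-"]]))
  expect_equal(b$rates[["s*+"]], 13.125)
  # binding/desensitization loop: kd- = k- d1- / d1+
  expect_equal(b$rates[["kd-"]], 40000 * 25 / 300)
  # deep-desensitized rung: s2+ = s+ d2*+ d2- / (d2+ d2*-)
  expect_equal(b$rates[["s2+"]],
               0.07 * 120 * r[["d2-"]] / (120 * r[["d2*-"]]))
  # non-dependent rates untouched
  expect_equal(b$rates[["beta"]], 8000)
  expect_equal(b$rates[["s+"]], 0.07)
  expect_equal(nrow(b$adjustment), 3)
})

test_that("per-trial shutting rates are absorbed by the TARP activation rate", {
  for (tr in c(0L, 4L, 8L)) {
    sch <- build_trial_scheme("TARP", tr)
    alpha <- mutant_trials()$alpha[mutant_trials()$trial == tr]
    # open cycle with layer-specific shutting:
    # s*+ = s+ beta_s s*- alpha / (beta s- alpha_s)
    expect_equal(sch$rates[["s*+"]], 13.125 * alpha / 3000,
                 tolerance = 1e-10)
  }
})

test_that("the slow-unbinding alternate balances to the expected rates", {
  ab <- build_trial_scheme("alt-binding", 7)
  # bound-pair rung compensates the 10x slower active-layer unbinding
  expect_equal(ab$rates[["sb+"]], 0.7, tolerance = 1e-9)
  expect_equal(ab$rates[["kd*-"]], ab$rates[["kd-"]] / 10,
               tolerance = 1e-9)
  expect_lt(max(abs(cycle_imbalance(ab)$ratio - 1)), 1e-10)
})

test_that("unbalanced cycles without a dependent rate are refused", {
  expect_error(
    enforce_microscopic_reversibility(build_scheme("TARP"),
                                      dependent_rates = "kd-"),
    "no dependent rate")
  expect_error(
    enforce_microscopic_reversibility(build_scheme("TARP"),
                                      dependent_rates = "nope"),
    "not in scheme")
})

test_that("the TARP-less scheme balances by adjusting only kd-", {
  nt <- enforce_microscopic_reversibility(build_scheme("noTARP"))
  expect_equal(nt$adjustment$rate, "kd-")
  expect_equal(nt$adjustment$printed, 2500)
  other <- setdiff(names(nt$rates), "kd-")
  expect_identical(nt$rates[other], build_scheme("noTARP")$rates[other])
})
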