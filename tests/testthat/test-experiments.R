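# kinetics summary is computed once and inspected by several tests
ks <- exp_kinetics_summary(7)
nt_row <- ks$summary[ks$summary$variant == "noTARP", ]
wt_row <- ks$summary[ks$summary$variant == "TARP", ]

test_that("the TARP layer boosts peak opening and steady-state current", {
  expect_gt(wt_row$peak_popen, nt_row$peak_popen)
  expect_gt(wt_row$peak_current, nt_row$peak_current)
  expect_gt(wt_row$Iss_pct, nt_row$Iss_pct)
})

test_that("the TARP layer slows entry to desensitization", {
  expect_lt(wt_row$k_des, 0.9 * nt_row$k_des)
})

test_that("TARP deactivation gains a pronounced slow component", {
  expect_gt(wt_row$deact_slow_fraction, 0.10)
  expect_lt(nt_row$deact_slow_fraction, 0.05)
  expect_lt(wt_row$k_deact, nt_row$k_deact)
})

test_that("recovery fits choose the overshoot model only with TARPs", {
  expect_equal(ks$fits$noTARP$recovery$model, "HH")
  expect_false(ks$fits$noTARP$recovery$overshoot)
  expect_equal(ks$fits$TARP$recovery$model, "biexponential")
  # the underlying recovery rate is of the same order with and without
  # the TARP layer (the apparent speed-up is the superactivation
  # component, not a change in desensitized-state exit)
  expect_gt(ks$fits$TARP$recovery$k_rec, 0.3 * nt_row$k_rec)
  expect_lt(ks$fits$TARP$recovery$k_rec, 1.5 * nt_row$k_rec)
})

test_that("conditioning length grows the overshoot only with TARPs", {
  lens <- c(0.05, 0.2, 0.4, 0.9)
  ro <- exp_recovery_overshoot("TARP", 7, conditioning_lengths = lens)
  expect_true(ro$overshoot)
  expect_true(all(diff(ro$table$ratio) > 0))
  ron <- exp_recovery_overshoot("noTARP", 7, conditioning_lengths = lens)
  expect_false(ron$overshoot)
  expect_true(all(ron$table$ratio <= 1.005))
})

test_that("the overshoot is larger for faster-recovering mutants", {
  lens <- c(0.2, 0.6)
  r8 <- exp_recovery_overshoot("TARP", 8, conditioning_lengths = lens)
  r4 <- exp_recovery_overshoot("TARP", 4, conditioning_lengths = lens)
  expect_gt(r8$max_ratio, r4$max_ratio)
})

test_that("superactivation requires the TARP layer and grows without
           desensitization", {
  sa <- exp_superactivation(7, duration = 5)
  s <- sa$summary
  tarp <- s$magnitude_pct[s$variant == "TARP"]
  ctz <- s$magnitude_pct[s$variant == "TARP+CTZ"]
  expect_gt(tarp, 1)
  expect_gt(ctz, 2 * tarp)
  expect_lt(s$magnitude_pct[s$variant == "noTARP"], 0.5)
  expect_lt(s$magnitude_pct[s$variant == "noTARP+CTZ"], 2)
  # development rate of order 1-3 per second
  expect_gt(s$rate[s$variant == "TARP"], 0.5)
  expect_lt(s$rate[s$variant == "TARP"], 6)
})

test_that("superactivation is stronger for fast-recovering mutants", {
  mag <- vapply(c(0L, 8L), function(tr) {
    sch <- build_trial_scheme("TARP", tr)
    superactivation(simulate_protocol(
      sch, make_pulse(5, 0.01, post = 0.1)))$magnitude_pct
  }, numeric(1))
  expect_gt(mag[2], mag[1])
})

test_that("trains depress TARP-less receptors and superactivate complexes", {
  tn <- exp_trains(7, frequencies = 200, train_duration = 1)
  s <- tn$summary
  nt <- s[s$variant == "noTARP", ]
  wt <- s[s$variant == "TARP", ]
  expect_lt(nt$delta_q_pct, 0)
  expect_true(nt$monotone_depression)
  expect_gt(wt$delta_q_pct, 0)
  expect_gt(wt$repotentiation_pct, 5)
})

test_that("kainate efficacy is boosted disproportionately by TARPs", {
  ka <- exp_kainate_ratio(7)
  expect_gt(ka$ratio_increase, 1.5)
  expect_true(all(ka$summary$ka_glu_ratio < 1))
})

test_that("the steady-state dose-response curve is left-shifted by TARPs", {
  ec_t <- steady_state_response(wt_tarp)$ec50
  ec_n <- steady_state_response(wt_notarp)$ec50
  expect_lt(ec_t, 0.9 * ec_n)
})

test_that("the mutant series links recovery rate to the steady-state boost", {
  mc <- exp_mutant_correlation("TARP", trials = c(0L, 2L, 4L, 6L, 8L))
  expect_gt(mc$slope, 0)
  expect_equal(mc$spearman_rho, 1)
  expect_true(mc$monotone)
  expect_error(exp_mutant_correlation("TARP", trials = 7L), "two trials")
})
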