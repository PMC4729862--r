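test_that("synthesis is a pure function of its seed", {
  pr <- make_pulse(0.02, 0.01, post = 0.01)
  a <- synthesize_trace(wt_notarp, pr, noise = noise_model(0.02, 7))
  b <- synthesize_trace(wt_notarp, pr, noise = noise_model(0.02, 7))
  expect_identical(a$current, b$current)
  c2 <- synthesize_trace(wt_notarp, pr, noise = noise_model(0.02, 8))
  expect_false(identical(a$current, c2$current))
})

test_that("solution exchange produces the configured 10-90% rise time", {
  pr <- make_pulse(0.05, 0.01, post = 0.01)
  syn <- synthesize_trace(wt_notarp, pr,
                          acq = acquisition_model(exchange_time = 3e-4),
                          noise = noise_model(0, 1))
  cu <- syn$clean
  pk <- max(cu)
  t10 <- syn$time[which(cu >= 0.1 * pk)[1]]
  t90 <- syn$time[which(cu >= 0.9 * pk)[1]]
  expect_gt((t90 - t10) * 1e6, 270)
  expect_lt((t90 - t10) * 1e6, 330)
})

test_that("without exchange or noise the output is the resampled model", {
  pr <- make_pulse(0.02, 0.01, post = 0.01)
  syn <- synthesize_trace(
    wt_notarp, pr,
    acq = acquisition_model(sample_rate = 20000, filter_cutoff = 10000,
                            exchange_time = 0),
    noise = noise_model(0, 1))
  ref <- simulate_protocol(wt_notarp, pr)
  ref_cur <- ref$current[match(signif(syn$time, 10),
                               signif(ref$time, 10))]
  # away from the concentration steps the anti-alias filter is inert
  edges <- c(0.01, 0.03)
  away <- vapply(syn$time, function(t)
    all(abs(t - edges) > 1e-3), logical(1))
  expect_lt(max(abs(syn$clean[away] - ref_cur[away])), 1e-4)
})

test_that("rundown scales sweeps geometrically", {
  pr <- make_pulse(0.02, 0.01, post = 0.01)
  syn <- synthesize_trace(
    wt_notarp, pr, acq = acquisition_model(rundown = 0.05),
    noise = noise_model(0, 1), n_sweeps = 4)
  pks <- apply(syn$current, 2, max)
  expect_equal(pks / pks[1], 0.95^(0:3), tolerance = 1e-10)
})

test_that("noise is band-limited by the acquisition filter", {
  pr <- make_pulse(0.05, 0.01, post = 0.02)
  syn <- synthesize_trace(
    wt_notarp, pr,
    acq = acquisition_model(filter_cutoff = 2000),
    noise = noise_model(0.1, 21))
  noise <- syn$current[, 1] - syn$clean   # the additive component
  spec <- stats::spec.pgram(noise, plot = FALSE, taper = 0)
  f_hz <- spec$freq * 20000
  in_band <- mean(spec$spec[f_hz < 1500])
  out_band <- mean(spec$spec[f_hz > 4000])
  expect_gt(in_band / out_band, 30)
})

test_that("datasets cover the analysis battery with ground truth", {
  dir <- file.path(tempdir(), "tg-dataset")
  on.exit(unlink(dir, recursive = TRUE))
  man <- make_dataset(dir, trial = 7, variants = "noTARP", n_sweeps = 2,
                      seed = 5,
                      recovery_intervals = c(0.01, 0.05, 0.2))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(all(file.exists(file.path(dir, man$file))))
  sidecars <- sub("\\.csv$", ".json", file.path(dir, man$file))
  expect_true(all(file.exists(sidecars)))
  expect_true(any(grepl("recovery", man$protocol)))
  expect_true(any(grepl("train", man$protocol)))
  expect_true(any(grepl("ctz", man$protocol)))
  gt <- jsonlite::read_json(sidecars[1])
  expect_equal(gt$trial, 7)
  expect_true(!is.null(gt$rates[["beta"]]))
  df <- utils::read.csv(file.path(dir, man$file[1]))
  expect_true(all(c("time", "clean", "sweep1", "sweep2") %in% names(df)))
})

test_that("noise-free parameter recovery is exact", {
  pr0 <- parameter_recovery(wt_notarp, n_seeds = 1, sd = 0,
                            intervals = c(0.01, 0.05, 0.15, 0.4))
  expect_true(all(pr0$mean_rel_error < 0.005))
  expect_true(all(pr0$pass))
})

test_that("extreme noise is reported as failure, not silently passed", {
  prx <- parameter_recovery(wt_notarp, n_seeds = 2, sd = 0.5,
                            intervals = c(0.01, 0.05, 0.15, 0.4))
  expect_false(all(prx$pass))
})
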