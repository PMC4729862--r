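#' Acquisition model for synthetic recordings
#'
#' Describes the recording chain emulated by [synthesize_trace()]:
#' sampling rate, low-pass filter cutoff, the 10-90% solution-exchange
#' time of the fast perfusion system, and an optional per-sweep rundown.
#'
#' @param sample_rate Output sampling rate (Hz), default 20 kHz.
#' @param filter_cutoff Low-pass cutoff (Hz), default 10 kHz; must not
#'   exceed the Nyquist frequency of `sample_rate`.
#' @param exchange_time 10-90% solution exchange time (s), default
#'   300 microseconds.
#' @param rundown Fractional loss of peak current per sweep (default 0).
#' @return An object of class `acquisition_model`.
#' @export
acquisition_model <- function(sample_rate = 20000, filter_cutoff = 10000,
                              exchange_time = 3e-4, rundown = 0) {
  stopifnot(sample_rate > 0, filter_cutoff > 0, exchange_time >= 0,
            rundown >= 0, rundown < 1)
  if (filter_cutoff > sample_rate / 2)
    stop("filter cutoff must not exceed sample_rate / 2", call. = FALSE)
  structure(list(sample_rate = sample_rate, filter_cutoff = filter_cutoff,
                 exchange_time = exchange_time, rundown = rundown),
            class = "acquisition_model")
}

#' Noise model for synthetic recordings
#'
#' @param sd Additive Gaussian noise standard deviation, as a fraction of
#'   the clean peak current (default 0.02).
#' @param seed Integer seed; all noise is generated reproducibly from it.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sd = 0.02, seed = 1L) {
  stopifnot(sd >= 0)
  structure(list(sd = sd, seed = as.integer(seed)), class = "noise_model")
}

# error-function concentration ramp: smooths each segment boundary with
# the 10-90% exchange time, then re-discretizes onto a fine staircase so
# the master equation can still be propagated piecewise
smoothed_protocol <- function(protocol, exchange_time, dt_fine) {
  if (exchange_time <= 0) {
    pr <- protocol; pr$dt <- dt_fine
    return(pr)
  }
  sigma <- exchange_time / (2 * stats::qnorm(0.9))
  seg <- protocol$segments
  edges <- cumsum(seg$duration)
  total <- edges[length(edges)]
  bounds <- edges[-length(edges)]
  # fine partition only within +/- 4 sigma of each concentration step;
  # elsewhere the concentration is constant to excellent approximation
  cuts <- sort(unique(c(0, total,
                        unlist(lapply(bounds, function(b)
                          seq(b - 4 * sigma, b + 4 * sigma,
                              by = dt_fine))))))
  cuts <- cuts[cuts >= 0 & cuts <= total]
  if (cuts[length(cuts)] < total) cuts <- c(cuts, total)
  mids <- (cuts[-1] + cuts[-length(cuts)]) / 2
  conc <- rep(seg$concentration[1], length(mids))
  for (i in seq_along(bounds)) {
    step <- seg$concentration[i + 1] - seg$concentration[i]
    conc <- conc + step * stats::pnorm(mids, mean = bounds[i], sd = sigma)
  }
  concentration_protocol(
    data.frame(duration = diff(cuts), concentration = conc),
    label = paste(protocol$label, "(smoothed)"), dt = dt_fine)
}

butter_lowpass <- function(x, cutoff, fs) {
  bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

#' Generate a synthetic patch-clamp trace
#'
#' Turns a deterministic model trace into a realistic "recorded" sweep:
#' the scheme is re-simulated on a fine grid with the concentration
#' steps smoothed by an error-function solution-exchange ramp (or, with
#' `mode = "convolve"`, the clean current is smoothed post hoc), the
#' current is low-pass filtered and resampled to the acquisition rate,
#' and filtered Gaussian noise is added.  Everything is a pure function
#' of (scheme, protocol, acquisition, noise seed).
#'
#' @param scheme A balanced `kinetic_scheme`.
#' @param protocol A `concentration_protocol`.
#' @param acq An [acquisition_model()].
#' @param noise A [noise_model()].
#' @param n_sweeps Number of noise realizations (sweeps) to generate.
#' @param mode `"resimulate"` (default: physically consistent exchange
#'   ramp at the concentration level) or `"convolve"` (cheap fallback:
#'   Gaussian smoothing of the clean current).
#' @param dt_fine Internal simulation step (s) before filtering and
#'   resampling (default 1e-5, i.e. 100 kHz).
#' @return Object of class `synthetic_trace`: list with `time` (sampled
#'   grid), `current` (matrix, one column per sweep), `clean` (noise-free
#'   filtered current including rundown of sweep 1), `ground_truth`
#'   (scheme/protocol metadata and generating parameters).
#' @export
synthesize_trace <- function(scheme, protocol, acq = acquisition_model(),
                             noise = noise_model(), n_sweeps = 1,
                             mode = c("resimulate", "convolve"),
                             dt_fine = 1e-5) {
  mode <- match.arg(mode)
  stopifnot(inherits(acq, "acquisition_model"),
            inherits(noise, "noise_model"), n_sweeps >= 1)
  if (mode == "resimulate") {
    pr_fine <- smoothed_protocol(protocol, acq$exchange_time, dt_fine)
    tr <- simulate_protocol(scheme, pr_fine)
    cur_fine <- tr$current
    t_fine <- tr$time
  } else {
    pr <- protocol; pr$dt <- dt_fine
    tr <- simulate_protocol(scheme, pr)
    cur_fine <- tr$current
    t_fine <- tr$time
    if (acq$exchange_time > 0) {
      sigma <- acq$exchange_time / (2 * stats::qnorm(0.9))
      half_w <- ceiling(4 * sigma / dt_fine)
      kern <- stats::dnorm(seq(-half_w, half_w) * dt_fine, sd = sigma)
      kern <- kern / sum(kern)
      cur_fine <- stats::filter(c(rep(cur_fine[1], half_w), cur_fine,
                                  rep(cur_fine[length(cur_fine)], half_w)),
                                kern, sides = 2)
      cur_fine <- as.numeric(cur_fine[(half_w + 1):(half_w +
                                                      length(t_fine))])
    }
  }
  fs_fine <- 1 / dt_fine
  filtered <- if (acq$filter_cutoff < fs_fine / 2)
    butter_lowpass(cur_fine, acq$filter_cutoff, fs_fine) else cur_fine
  stride <- max(1L, as.integer(round(fs_fine / acq$sample_rate)))
  keep <- seq(1, length(t_fine), by = stride)
  t_out <- t_fine[keep]
  clean <- filtered[keep]
  # noise amplitude is referenced to the peak current; for silent traces
  # (no response) fall back to absolute units
  peak <- max(abs(clean))
  if (peak == 0) peak <- 1

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(noise$seed)
  sweeps <- vapply(seq_len(n_sweeps), function(sw) {
    scale <- (1 - acq$rundown)^(sw - 1)
    if (noise$sd > 0) {
      w <- stats::rnorm(length(t_fine))
      w <- if (acq$filter_cutoff < fs_fine / 2)
        butter_lowpass(w, acq$filter_cutoff, fs_fine) else w
      w <- w[keep]
      w <- w / stats::sd(w) * noise$sd * peak
    } else {
      w <- numeric(length(keep))
    }
    clean * scale + w
  }, numeric(length(keep)))

  structure(
    list(time = t_out, current = sweeps, clean = clean,
         protocol = protocol,
         ground_truth = list(variant = scheme$variant,
                             trial = scheme$trial,
                             rates = scheme$rates,
                             acquisition = acq, noise = noise,
                             mode = mode)),
    class = "synthetic_trace")
}

#' @export
print.synthetic_trace <- function(x, ...) {
  cat("Synthetic trace [", x$ground_truth$variant, "]: ",
      length(x$time), " samples x ", ncol(x$current), " sweep(s); ",
      "noise sd ", x$ground_truth$noise$sd, ", exchange ",
      x$ground_truth$acquisition$exchange_time * 1e6, " us\n", sep = "")
  invisible(x)
}

#' Generate a synthetic dataset covering the analysis stack
#'
#' Writes CSV traces plus JSON ground-truth sidecars for the standard
#' protocol battery (desensitization, deactivation, two-pulse recovery
#' series, long-pulse superactivation, CTZ, train), for the chosen
#' variants and trial, so every analysis operation has matched noisy
#' fixtures with known generating parameters.
#'
#' @param dir Output directory (created if needed).
#' @param trial Mutant trial id.
#' @param variants Scheme variants to include.
#' @param n_sweeps Noise realizations per protocol.
#' @param seed Base seed; each protocol uses `seed + index`.
#' @param acq An [acquisition_model()].
#' @param sd Noise standard deviation (fraction of peak).
#' @param recovery_intervals Intervals for the two-pulse series (s).
#' @return Invisibly, a manifest data frame (also written as
#'   `manifest.csv`).
#' @export
make_dataset <- function(dir, trial = 7, variants = c("noTARP", "TARP"),
                         n_sweeps = 3, seed = 1,
                         acq = acquisition_model(), sd = 0.02,
                         recovery_intervals = c(0.005, 0.01, 0.02, 0.035,
                                                0.06, 0.1, 0.15, 0.25,
                                                0.4, 0.6)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  idx <- 0L
  for (v in variants) {
    sch <- build_trial_scheme(v, trial)
    protos <- list(
      desensitization = make_pulse(0.5, 0.01, post = 0.1),
      deactivation = make_pulse(0.001, 0.01, post = 0.05),
      long_pulse = make_pulse(5, 0.01, post = 0.2),
      train = make_train(0.001, 200, 60, 0.01))
    for (iv in recovery_intervals)
      protos[[sprintf("recovery_%04.0fms", iv * 1000)]] <-
        make_two_pulse(0.5, iv, 0.01, 0.01, post = 0.02)
    if (v %in% c("TARP", "noTARP")) {
      ctz_variant <- paste0(v, "+CTZ")
      protos[["ctz_long_pulse"]] <- make_pulse(5, 0.01, post = 0.2)
    }
    for (pn in names(protos)) {
      idx <- idx + 1L
      use_scheme <- if (pn == "ctz_long_pulse")
        build_trial_scheme(paste0(v, "+CTZ"), trial) else sch
      syn <- synthesize_trace(use_scheme, protos[[pn]], acq = acq,
                              noise = noise_model(sd, seed + idx),
                              n_sweeps = n_sweeps)
      base <- sprintf("%s_%s", gsub("[^A-Za-z0-9]", "", v), pn)
      df <- data.frame(time = syn$time, clean = syn$clean)
      for (sw in seq_len(ncol(syn$current)))
        df[[paste0("sweep", sw)]] <- syn$current[, sw]
      utils::write.csv(df, file.path(dir, paste0(base, ".csv")),
                       row.names = FALSE)
      jsonlite::write_json(
        list(variant = use_scheme$variant, trial = trial,
             protocol = protos[[pn]]$segments,
             rates = as.list(syn$ground_truth$rates),
             noise_sd = sd, seed = seed + idx,
             n_sweeps = n_sweeps,
             exchange_time = acq$exchange_time),
        file.path(dir, paste0(base, ".json")), auto_unbox = TRUE,
        digits = NA)
      manifest[[idx]] <- data.frame(file = paste0(base, ".csv"),
                                    variant = use_scheme$variant,
                                    protocol = pn, seed = seed + idx)
    }
  }
  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Parameter recovery from synthetic noisy traces
#'
#' End-to-end validation of the analysis stack: generates noisy sweeps of
#' the standard protocols for one scheme, runs the same fits used on
#' clean model output, and reports the relative error of each recovered
#' parameter against the noise-free values.
#'
#' @param scheme A balanced `kinetic_scheme` (default: TARP-less
#'   wild-type proxy, whose decays exercise every fit).
#' @param n_seeds Number of independent noise realizations; errors are
#'   averaged over realizations.
#' @param seed Base seed for the noise generator.
#' @param sd Noise standard deviation (fraction of peak).
#' @param acq An [acquisition_model()].
#' @param tolerance Relative error (fraction) below which a parameter
#'   counts as recovered.
#' @param intervals Recovery intervals (s).
#' @return A data frame with one row per parameter (`k_des`, `k_deact`,
#'   `k_rec`, plus `superactivation_pct` for two-layer schemes): truth
#'   (from the noise-free trace), mean estimate, mean relative error,
#'   `pass`.
#' @export
parameter_recovery <- function(scheme = build_trial_scheme("noTARP", 7),
                               n_seeds = 5, seed = 1, sd = 0.02,
                               acq = acquisition_model(),
                               tolerance = 0.1,
                               intervals = c(0.005, 0.01, 0.02, 0.035,
                                             0.06, 0.1, 0.15, 0.25, 0.4,
                                             0.6)) {
  two_layer <- any(scheme$states$layer == "S")
  protos <- list(
    des = make_pulse(0.5, 0.01, post = 0.1),
    deact = make_pulse(0.001, 0.01, post = 0.05))
  if (two_layer) protos$long <- make_pulse(5, 0.01, post = 0.2)
  rec_protos <- lapply(intervals, function(iv)
    make_two_pulse(0.5, iv, 0.01, 0.01, post = 0.02))

  # one simulation per protocol; each sweep is an independent noise draw
  syn <- lapply(seq_along(protos), function(i)
    synthesize_trace(scheme, protos[[i]], acq = acq,
                     noise = noise_model(sd, seed + i),
                     n_sweeps = n_seeds))
  names(syn) <- names(protos)
  syn_rec <- lapply(seq_along(rec_protos), function(i)
    synthesize_trace(scheme, rec_protos[[i]], acq = acq,
                     noise = noise_model(sd, seed + 100 + i),
                     n_sweeps = n_seeds))

  measure <- function(col) {
    get_cur <- function(s) if (is.na(col)) s$clean else s$current[, col]
    wrap <- function(s) list(time = s$time, current = get_cur(s),
                             protocol = s$protocol)
    out <- c(
      k_des = fit_desensitization(wrap(syn$des))$weighted_rate,
      k_deact = fit_deactivation(wrap(syn$deact))$weighted_rate)
    resp <- vapply(syn_rec, function(s) {
      seg <- s$protocol$segments
      starts <- cumsum(c(0, seg$duration[-nrow(seg)]))
      cur <- get_cur(s)
      pk1 <- max(cur[s$time >= starts[2] & s$time <= starts[3]])
      pk2 <- max(cur[s$time >= starts[4] & s$time <= starts[5]])
      pk2 / pk1
    }, numeric(1))
    rec_fit <- if (any(resp > 1.02)) fit_suprarecovery(intervals, resp)
      else fit_recovery(intervals, resp)
    out["k_rec"] <- rec_fit$k_rec
    if (two_layer)
      out["superactivation_pct"] <-
        superactivation(wrap(syn$long))$magnitude_pct
    out
  }

  truth <- measure(NA)
  ests <- vapply(seq_len(n_seeds), function(sw) measure(sw), truth)
  est_mean <- rowMeans(ests)
  rel_err <- rowMeans(abs(sweep(ests, 1, truth, "-")) / abs(truth))
  data.frame(parameter = names(truth), truth = unname(truth),
             estimate = unname(est_mean),
             mean_rel_error = unname(rel_err),
             pass = unname(rel_err <= tolerance))
}
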