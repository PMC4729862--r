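#' Superactivation of a long-pulse trace
#'
#' Superactivation is the slow, activity-dependent growth of the
#' steady-state current during a sustained (>= 1 s) agonist application,
#' reflecting accumulation of receptor-TARP complexes in the high-open-
#' probability, high-conductance state.  In the default mode the
#' magnitude is the excess of the late steady-state amplitude over the
#' trough of the current following the initial peak, normalized to the
#' peak current (in %).  With desensitization blocked (`ctz_mode = TRUE`)
#' there is no trough: the initial fast peak (within the first 2 ms of
#' application) is the baseline, and the magnitude is the late amplitude
#' relative to that initial peak.  The rate is taken from an exponential
#' fit of the rising phase (trough/initial peak to the end of the
#' application).
#'
#' @param trace A `sim_trace` (or compatible list) from a long agonist
#'   application.
#' @param ctz_mode Logical; use the desensitization-blocked definition.
#' @param trough_window Fraction of the application duration, after the
#'   initial peak + 2 ms, searched for the trough (default 0.5).
#' @param steady_fraction Final fraction of the application averaged as
#'   the late steady-state amplitude.
#' @return Object of class `superactivation_result`: list with
#'   `magnitude_pct`, `rate` (s^-1, `NA` when the magnitude is ~0),
#'   `reference` (`"trough"` or `"initial-peak"`), plus the underlying
#'   `peak`, `trough`, `steady` values and the rise `fit` (an `exp_fit`
#'   or `NULL`).
#' @export
superactivation <- function(trace, ctz_mode = FALSE, trough_window = 0.5,
                            steady_fraction = 0.05) {
  seg <- trace$protocol$segments
  j <- which(seg$concentration > 0)[1]
  if (is.na(j)) stop("protocol has no agonist segment", call. = FALSE)
  starts <- cumsum(c(0, seg$duration[-nrow(seg)]))
  on <- starts[j]; off <- on + seg$duration[j]
  if (seg$duration[j] < 1)
    stop("superactivation needs an agonist application of at least 1 s",
         call. = FALSE)
  idx <- which(trace$time >= on & trace$time <= off)
  tt <- trace$time[idx]; cur_raw <- trace$current[idx]
  # peak/trough landmarks are read from a lightly smoothed copy (0.5 ms
  # running mean) so single-sample noise excursions do not bias the
  # magnitude; the steady state is already an average
  dt <- stats::median(diff(tt))
  w <- max(1L, round(5e-4 / dt))
  cur <- if (w > 1) {
    sm <- stats::filter(cur_raw, rep(1 / w, w), sides = 2)
    ifelse(is.na(sm), cur_raw, as.numeric(sm))
  } else cur_raw
  steady <- mean(cur_raw[tt >= off - steady_fraction * (off - on)])

  if (ctz_mode) {
    early <- which(tt <= on + 0.002)
    if (!length(early)) stop("no samples in the initial 2 ms", call. = FALSE)
    ref <- max(cur[early])
    t_ref <- tt[early][which.max(cur[early])]
    magnitude <- 100 * (steady - ref) / ref
    reference <- "initial-peak"
    trough <- NA_real_
    peak <- ref
  } else {
    # the reference peak is the initial activation peak (within the
    # first 50 ms); for strongly superactivating traces the late current
    # can exceed it, so a global maximum would be the wrong landmark
    early <- tt <= on + 0.05
    peak <- max(cur[early])
    t_peak <- tt[early][which.max(cur[early])]
    search <- which(tt > t_peak + 0.002 & tt <= on + trough_window * (off - on))
    if (!length(search))
      stop("no identifiable trough after the initial peak", call. = FALSE)
    i_tr <- search[which.min(cur[search])]
    trough <- cur[i_tr]
    t_ref <- tt[i_tr]
    magnitude <- 100 * (steady - trough) / peak
    reference <- "trough"
  }

  fit <- NULL
  rate <- NA_real_
  if (magnitude > 0.05) {
    rise <- tryCatch(
      fit_exponentials(tt, cur_raw, window = c(t_ref, off),
                       n_components = if (ctz_mode) 1 else 2),
      error = function(e) NULL)
    if (!is.null(rise)) {
      fit <- rise
      rate <- rise$weighted_rate
    }
  } else {
    magnitude <- max(magnitude, 0)
  }
  structure(
    list(magnitude_pct = magnitude, rate = rate, reference = reference,
         peak = peak, trough = trough, steady = steady, fit = fit),
    class = "superactivation_result")
}

#' @export
print.superactivation_result <- function(x, ...) {
  cat(sprintf("Superactivation: %.3g%% (ref: %s)", x$magnitude_pct,
              x$reference))
  if (!is.na(x$rate)) cat(sprintf(", rate %.3g s^-1", x$rate))
  cat("\n")
  invisible(x)
}

#' Change in charge transfer over a pulse train
#'
#' Integrates the current over each pulse window (pulse onset to the next
#' onset) and compares the charge transferred late in the train with that
#' at the beginning:
#' `dQ = (Q2 - Q1) / Q1 * 100`, with `Q1` the summed charge of the first
#' five pulses and `Q2` that of the last five.  Positive values indicate
#' activity-dependent potentiation (superactivation), negative values
#' depression.
#'
#' @param trace A `sim_trace` from a train protocol.
#' @param onsets Pulse onset times (s); defaults to
#'   [pulse_onsets()] of the trace's protocol.
#' @param n_ref Number of pulses averaged at each end (default 5).
#' @return List with `delta_q_pct`, `q_pulse` (charge per pulse window),
#'   `q1`, `q2`.
#' @export
charge_transfer_change <- function(trace, onsets = NULL, n_ref = 5) {
  if (is.null(onsets)) onsets <- pulse_onsets(trace$protocol)
  if (length(onsets) < 2 * n_ref)
    stop("need at least ", 2 * n_ref, " pulses", call. = FALSE)
  if (any(diff(onsets) <= 0))
    stop("pulse windows overlap or are unordered", call. = FALSE)
  period <- stats::median(diff(onsets))
  bounds <- c(onsets, onsets[length(onsets)] + period)
  q <- vapply(seq_along(onsets), function(i) {
    idx <- which(trace$time >= bounds[i] & trace$time < bounds[i + 1])
    sum(trace$current[idx]) * trace$protocol$dt
  }, numeric(1))
  q1 <- sum(q[seq_len(n_ref)])
  q2 <- sum(q[seq(length(q) - n_ref + 1, length(q))])
  list(delta_q_pct = 100 * (q2 - q1) / q1, q_pulse = q, q1 = q1, q2 = q2)
}

#' Per-pulse peak currents of a train trace
#'
#' @inheritParams charge_transfer_change
#' @return Numeric vector of peak current in each pulse window.
#' @export
train_peaks <- function(trace, onsets = NULL) {
  if (is.null(onsets)) onsets <- pulse_onsets(trace$protocol)
  period <- if (length(onsets) > 1) stats::median(diff(onsets)) else
    protocol_duration(trace$protocol) - onsets
  bounds <- c(onsets, onsets[length(onsets)] + period)
  vapply(seq_along(onsets), function(i) {
    idx <- which(trace$time >= bounds[i] & trace$time < bounds[i + 1])
    max(trace$current[idx])
  }, numeric(1))
}
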