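#' Concentration protocols
#'
#' A concentration protocol is a piecewise-constant agonist concentration
#' timeline: an ordered set of segments, each with a duration (s) and a
#' concentration (M), plus the sample interval of the output grid
#' (default 5e-5 s, i.e. 20 kHz).
#'
#' @param segments Data frame with columns `duration` (s, > 0) and
#'   `concentration` (M, >= 0).
#' @param label Optional protocol label.
#' @param dt Sample interval in seconds.
#' @return An object of class `concentration_protocol`.
#' @seealso [make_pulse()], [make_two_pulse()], [make_train()]
#' @export
concentration_protocol <- function(segments, label = "", dt = 5e-5) {
  stopifnot(is.data.frame(segments),
            all(c("duration", "concentration") %in% names(segments)))
  if (any(segments$duration <= 0))
    stop("segment durations must be positive", call. = FALSE)
  if (any(segments$concentration < 0))
    stop("segment concentrations must be non-negative", call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  structure(list(segments = segments[, c("duration", "concentration")],
                 label = label, dt = dt),
            class = "concentration_protocol")
}

#' @export
print.concentration_protocol <- function(x, ...) {
  cat("Concentration protocol", if (nzchar(x$label)) sQuote(x$label), ":",
      nrow(x$segments), "segments,",
      format(sum(x$segments$duration)), "s total, dt =", format(x$dt),
      "s\n")
  invisible(x)
}

#' Total protocol duration (s)
#' @param protocol A `concentration_protocol`.
#' @return Numeric scalar.
#' @export
protocol_duration <- function(protocol) sum(protocol$segments$duration)

#' Concentration at given times
#'
#' @param protocol A `concentration_protocol`.
#' @param times Numeric vector of times (s) within the protocol.
#' @return Concentrations (M) at each time.
#' @export
protocol_concentration <- function(protocol, times) {
  edges <- cumsum(protocol$segments$duration)
  idx <- findInterval(times, c(0, edges[-length(edges)]),
                      rightmost.closed = FALSE)
  idx[idx < 1] <- 1L
  idx[idx > nrow(protocol$segments)] <- nrow(protocol$segments)
  protocol$segments$concentration[idx]
}

#' Single agonist pulse
#'
#' Three-segment protocol: baseline, agonist application, washout.  The
#' standard desensitization and deactivation measurements use 500 ms and
#' 1 ms applications of 10 mM glutamate respectively.
#'
#' @param duration Pulse duration (s).
#' @param concentration Agonist concentration during the pulse (M).
#' @param pre Baseline before the pulse (s), default 10 ms.
#' @param post Washout after the pulse (s), default 200 ms.
#' @param dt Sample interval (s).
#' @return A `concentration_protocol`.
#' @export
#' @examples
#' make_pulse(0.5, 0.01)     # desensitization protocol
#' make_pulse(0.001, 0.01)   # deactivation protocol
make_pulse <- function(duration, concentration, pre = 0.01, post = 0.2,
                       dt = 5e-5) {
  stopifnot(duration > 0, pre > 0, post > 0)
  concentration_protocol(
    data.frame(duration = c(pre, duration, post),
               concentration = c(0, concentration, 0)),
    label = sprintf("pulse %gs @ %g M", duration, concentration), dt = dt)
}

#' Two-pulse recovery protocol
#'
#' Five-segment protocol: baseline, conditioning pulse, variable
#' inter-pulse interval, test pulse, washout.  Used to measure recovery
#' from desensitization and (with long conditioning pulses) suprarecovery.
#'
#' @param conditioning Conditioning pulse duration (s).
#' @param interval Inter-pulse interval in zero agonist (s).
#' @param test Test pulse duration (s).
#' @param concentration Agonist concentration (M) for both pulses.
#' @inheritParams make_pulse
#' @return A `concentration_protocol`.
#' @export
#' @examples
#' make_two_pulse(0.4, 0.2, 0.01, 0.01)  # suprarecovery back-extrapolation
make_two_pulse <- function(conditioning, interval, test = 0.01,
                           concentration = 0.01, pre = 0.01, post = 0.05,
                           dt = 5e-5) {
  stopifnot(conditioning > 0, interval > 0, test > 0, pre > 0, post > 0)
  concentration_protocol(
    data.frame(duration = c(pre, conditioning, interval, test, post),
               concentration = c(0, concentration, 0, concentration, 0)),
    label = sprintf("two-pulse cond %gs, gap %gs", conditioning, interval),
    dt = dt)
}

#' Train of brief pulses
#'
#' Alternating agonist/washout segments mimicking repetitive synaptic
#' activity, e.g. 200 Hz trains of 1 ms pulses of 10 mM glutamate.
#'
#' @param pulse Pulse duration (s); must be shorter than the period
#'   `1/frequency`.
#' @param frequency Stimulation frequency (Hz).
#' @param n_pulses Number of pulses (>= 1).
#' @param concentration Agonist concentration (M).
#' @inheritParams make_pulse
#' @return A `concentration_protocol`.  The final inter-pulse gap is
#'   extended by `post`.
#' @export
#' @examples
#' make_train(0.001, 200, 50, 0.01)
make_train <- function(pulse, frequency, n_pulses, concentration,
                       pre = 0.01, post = 0.05, dt = 5e-5) {
  stopifnot(pulse > 0, frequency > 0, n_pulses >= 1, pre > 0, post > 0)
  if (pulse * frequency >= 1)
    stop("pulse duration must be shorter than the stimulation period ",
         "1/frequency", call. = FALSE)
  gap <- 1 / frequency - pulse
  n_pulses <- as.integer(n_pulses)
  durs <- c(pre, rep(c(pulse, gap), n_pulses))
  concs <- c(0, rep(c(concentration, 0), n_pulses))
  durs[length(durs)] <- gap + post
  concentration_protocol(
    data.frame(duration = durs, concentration = concs),
    label = sprintf("train %d x %gs @ %g Hz", n_pulses, pulse, frequency),
    dt = dt)
}

#' Onset times of the agonist pulses in a protocol
#'
#' @param protocol A `concentration_protocol`.
#' @return Numeric vector of times (s) at which a segment with non-zero
#'   concentration begins.
#' @export
pulse_onsets <- function(protocol) {
  seg <- protocol$segments
  starts <- cumsum(c(0, seg$duration[-nrow(seg)]))
  prev <- c(0, seg$concentration[-nrow(seg)])
  starts[seg$concentration > 0 & prev == 0]
}
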