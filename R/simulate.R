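# Segment propagation.  Within a constant-concentration segment the master
# equation dp/dt = t(Q) p has the exact solution p(t) = expm(t(Q) t) p0.
# The spectral form is used when the eigenbasis is well conditioned (it
# evaluates all sample times in one matrix product); otherwise the segment
# is propagated by repeated one-step matrix exponentials, which is exact
# for any step size.
propagate_segment <- function(Qt, p0, times, t_end) {
  n <- length(p0)
  occ <- NULL
  ok <- FALSE
  E <- tryCatch(eigen(Qt), error = function(e) NULL)
  if (!is.null(E)) {
    W <- tryCatch(solve(E$vectors, as.complex(p0)),
                  error = function(e) NULL)
    if (!is.null(W)) {
      all_t <- c(times, t_end)
      raw <- E$vectors %*% (exp(outer(E$values, all_t)) * W)
      raw <- Re(raw)
      sums <- colSums(raw)
      if (all(is.finite(raw)) && max(abs(sums - 1)) < 1e-8 &&
          min(raw) > -1e-8) {
        occ <- raw
        ok <- TRUE
      }
    }
  }
  if (!ok) {
    # fallback: exact stepping with the matrix exponential
    all_t <- c(times, t_end)
    occ <- matrix(0, n, length(all_t))
    p <- p0
    t_prev <- 0
    steps <- unique(signif(diff(c(0, all_t)), 12))
    props <- lapply(steps, function(h)
      if (h > 0) pracma::expm(Qt * h) else diag(n))
    names(props) <- format(steps, digits = 12)
    for (i in seq_along(all_t)) {
      h <- signif(all_t[i] - t_prev, 12)
      if (h > 0) p <- props[[format(h, digits = 12)]] %*% p
      occ[, i] <- p
      t_prev <- all_t[i]
    }
  }
  occ[occ < 0] <- 0
  occ <- sweep(occ, 2, colSums(occ), "/")
  list(occ = occ[, seq_along(times), drop = FALSE],
       p_end = occ[, length(times) + 1L])
}

#' Simulate a scheme over a concentration protocol
#'
#' Integrates the master equation of a (balanced) kinetic scheme over a
#' piecewise-constant agonist protocol.  Within each segment the state
#' occupancies are propagated with the matrix exponential of the
#' generator, so the result is deterministic and independent of the
#' sample interval.
#'
#' @param scheme A balanced `kinetic_scheme` (see
#'   [enforce_microscopic_reversibility()]).
#' @param protocol A `concentration_protocol`.
#' @param initial Either `"equilibrium"` (stationary distribution at the
#'   first segment's concentration; the default, which for TARP schemes
#'   includes the few percent of basally superactive complexes) or a
#'   probability vector over states.
#' @param on_unbalanced What to do when the scheme is not balanced:
#'   `"warn"` (default), `"error"`, or `"ignore"`.
#' @return An object of class `sim_trace`: list with `time` (s),
#'   `occupancy` (time x state probability matrix), `popen` (summed open
#'   occupancy), `current` (occupancy weighted by normalized
#'   conductances), plus the protocol and scheme metadata.
#' @export
#' @examples
#' wt <- build_trial_scheme("TARP", 7)
#' tr <- simulate_protocol(wt, make_pulse(0.5, 0.01))
#' max(tr$current)
simulate_protocol <- function(scheme, protocol, initial = "equilibrium",
                              on_unbalanced = c("warn", "error", "ignore")) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            inherits(protocol, "concentration_protocol"))
  on_unbalanced <- match.arg(on_unbalanced)
  if (!isTRUE(scheme$balanced)) {
    msg <- "scheme is not balanced; run enforce_microscopic_reversibility()"
    if (on_unbalanced == "error") stop(msg, call. = FALSE)
    if (on_unbalanced == "warn") warning(msg, call. = FALSE)
  }
  seg <- protocol$segments
  m <- nrow(seg)
  edges <- cumsum(seg$duration)
  starts <- c(0, edges[-m])
  n <- nrow(scheme$states)

  if (identical(initial, "equilibrium")) {
    p <- equilibrium_occupancy(scheme, seg$concentration[1])
  } else {
    p <- as.numeric(initial)
    if (length(p) != n || abs(sum(p) - 1) > 1e-8 || min(p) < 0)
      stop("initial must be 'equilibrium' or a probability vector over ",
           n, " states", call. = FALSE)
    names(p) <- scheme$states$name
  }

  dt <- protocol$dt
  tgrid <- seq(0, edges[m] + dt * 1e-9, by = dt)
  occ <- matrix(NA_real_, length(tgrid), n,
                dimnames = list(NULL, scheme$states$name))
  occ[1, ] <- p
  eps <- dt * 1e-6
  # sample i (i > 1) belongs to segment j iff starts[j] < t_i <= edges[j]
  assign_seg <- findInterval(tgrid - eps, edges) + 1L
  assign_seg[1] <- 0L
  idx_by_seg <- split(seq_along(tgrid), factor(assign_seg, levels = 0:m))
  for (j in seq_len(m)) {
    idx <- idx_by_seg[[j + 1L]]
    Qt <- t(generator_matrix(scheme, seg$concentration[j]))
    res <- propagate_segment(Qt, p, tgrid[idx] - starts[j],
                             seg$duration[j])
    if (length(idx)) occ[idx, ] <- t(res$occ)
    p <- res$p_end
  }
  g <- scheme$states$conductance
  structure(
    list(time = tgrid, occupancy = occ,
         popen = as.numeric(occ %*% (g > 0)),
         current = as.numeric(occ %*% g),
         protocol = protocol,
         variant = scheme$variant, trial = scheme$trial,
         conductance = g),
    class = "sim_trace")
}

#' @export
print.sim_trace <- function(x, ...) {
  cat("Simulated trace [", x$variant,
      if (!is.na(x$trial)) paste0(" trial ", x$trial), "]: ",
      length(x$time), " samples over ", format(max(x$time)), " s; peak ",
      "current ", format(max(x$current), digits = 4), "\n", sep = "")
  invisible(x)
}

#' @param x A `sim_trace`.
#' @param what `"current"` or `"popen"`.
#' @param ... Passed to [graphics::plot()].
#' @rdname simulate_protocol
#' @export
plot.sim_trace <- function(x, what = c("current", "popen"), ...) {
  what <- match.arg(what)
  graphics::plot(x$time, x[[what]], type = "l", xlab = "time (s)",
                 ylab = if (what == "current") "normalized current"
                        else "open probability", ...)
  conc <- protocol_concentration(x$protocol, x$time)
  if (any(conc > 0))
    graphics::lines(x$time, max(x[[what]]) * 1.05 * (conc > 0) ,
                    col = "grey60", lty = 3)
  invisible(x)
}

#' Peak and steady-state current of a trace
#'
#' Peak is the maximum current within the window; steady state is the mean
#' over the final fraction (default 5%) of the window.  The default window
#' is the first agonist application segment of the protocol.
#'
#' @param trace A `sim_trace` (or any list with `time`, `current` and a
#'   `protocol`).
#' @param window Numeric `c(from, to)` in seconds, or `NULL` for the first
#'   non-zero-concentration segment.
#' @param steady_fraction Final fraction of the window averaged for the
#'   steady state.
#' @return List with `peak`, `steady`, and `ratio_pct` (steady/peak x 100).
#' @export
peak_and_steady <- function(trace, window = NULL, steady_fraction = 0.05) {
  if (is.null(window)) {
    seg <- trace$protocol$segments
    j <- which(seg$concentration > 0)[1]
    if (is.na(j)) stop("protocol has no agonist segment", call. = FALSE)
    starts <- cumsum(c(0, seg$duration[-nrow(seg)]))
    window <- c(starts[j], starts[j] + seg$duration[j])
  }
  idx <- which(trace$time >= window[1] & trace$time <= window[2])
  if (!length(idx)) stop("empty analysis window", call. = FALSE)
  cur <- trace$current[idx]
  peak <- max(cur)
  t_w <- trace$time[idx]
  ss_idx <- t_w >= window[2] - steady_fraction * diff(window)
  steady <- mean(cur[ss_idx])
  list(peak = peak, steady = steady, ratio_pct = 100 * steady / peak)
}
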