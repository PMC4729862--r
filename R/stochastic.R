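#' Stochastic single-channel simulation
#'
#' Gillespie-style continuous-time Markov jump simulation of `n_channels`
#' independent channels over a piecewise-constant concentration protocol.
#' Each channel draws exponential waiting times from its current state's
#' total exit rate and jumps with probabilities proportional to the
#' individual transition rates; the ensemble-mean occupancy is binned onto
#' the protocol's sample grid.  This is an independent oracle for the
#' deterministic matrix-exponential engine: for large ensembles the mean
#' occupancy converges to the master-equation solution with Monte-Carlo
#' error of order `1/sqrt(n_channels)`.
#'
#' @inheritParams simulate_protocol
#' @param n_channels Number of independent channels (>= 1).
#' @param seed Integer seed; the simulation is reproducible given the
#'   seed.
#' @return A `sim_trace` whose `occupancy` holds ensemble-mean state
#'   fractions (for `n_channels = 1`, a one-hot single-channel record).
#' @export
#' @examples
#' wt <- build_trial_scheme("noTARP", 7)
#' st <- stochastic_simulate(wt, make_pulse(0.005, 0.01, post = 0.02),
#'                           n_channels = 100, seed = 1)
stochastic_simulate <- function(scheme, protocol, n_channels, seed,
                                initial = "equilibrium") {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            inherits(protocol, "concentration_protocol"),
            n_channels >= 1)
  n_channels <- as.integer(n_channels)
  seg <- protocol$segments
  m <- nrow(seg)
  edges <- cumsum(seg$duration)
  starts <- c(0, edges[-m])
  n <- nrow(scheme$states)
  dt <- protocol$dt
  tgrid <- seq(0, edges[m] + dt * 1e-9, by = dt)
  nt <- length(tgrid)

  if (identical(initial, "equilibrium")) {
    p0 <- equilibrium_occupancy(scheme, seg$concentration[1])
  } else {
    p0 <- as.numeric(initial)
    stopifnot(length(p0) == n, abs(sum(p0) - 1) < 1e-8)
  }

  # per-segment exit rates and jump distributions
  seg_Q <- lapply(seg$concentration,
                  function(cc) generator_matrix(scheme, cc))

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)

  state <- sample.int(n, n_channels, replace = TRUE, prob = p0)
  t_ch <- numeric(n_channels)
  counts <- matrix(0L, nt, n)
  # grid index each channel has been recorded up to (exclusive)
  rec <- rep(1L, n_channels)

  for (j in seq_len(m)) {
    Q <- seg_Q[[j]]
    exit <- -diag(Q)
    P <- Q
    diag(P) <- 0
    P <- P / pmax(exit, .Machine$double.xmin)
    t_stop <- edges[j]
    active <- rep(TRUE, n_channels)
    while (any(active)) {
      ia <- which(active)
      rate <- exit[state[ia]]
      # absorbing in this segment (exit rate 0): jump straight to t_stop
      wait <- ifelse(rate > 0, stats::rexp(length(ia)) / rate, Inf)
      t_new <- t_ch[ia] + wait
      done <- t_new >= t_stop
      # record occupancy up to the jump (or segment end)
      upto <- pmin(t_new, t_stop)
      kmax <- pmin(findInterval(upto - 1e-12, tgrid) + 1L, nt + 1L)
      for (q in seq_along(ia)) {
        ch <- ia[q]
        if (rec[ch] < kmax[q]) {
          span <- rec[ch]:(kmax[q] - 1L)
          counts[cbind(span, state[ch])] <- counts[cbind(span, state[ch])] + 1L
          rec[ch] <- kmax[q]
        }
      }
      # advance the channels that jump within the segment
      jumpers <- ia[!done]
      if (length(jumpers)) {
        t_ch[jumpers] <- t_new[!done]
        from_states <- state[jumpers]
        for (s_from in unique(from_states)) {
          sel <- jumpers[from_states == s_from]
          state[sel] <- sample.int(n, length(sel), replace = TRUE,
                                   prob = P[s_from, ])
        }
      }
      t_ch[ia[done]] <- t_stop
      active[ia[done]] <- FALSE
    }
  }
  # record the final grid point(s)
  kmax <- rep(nt + 1L, n_channels)
  for (ch in which(rec < kmax)) {
    span <- rec[ch]:nt
    counts[cbind(span, state[ch])] <- counts[cbind(span, state[ch])] + 1L
    rec[ch] <- nt + 1L
  }

  occ <- counts / n_channels
  colnames(occ) <- scheme$states$name
  g <- scheme$states$conductance
  structure(
    list(time = tgrid, occupancy = occ,
         popen = as.numeric(occ %*% (g > 0)),
         current = as.numeric(occ %*% g),
         protocol = protocol, variant = scheme$variant,
         trial = scheme$trial, conductance = g,
         n_channels = n_channels, seed = seed),
    class = "sim_trace")
}
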