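# balanced wild-type proxy schemes, built once per test run
wt_tarp <- build_trial_scheme("TARP", 7)
wt_notarp <- build_trial_scheme("noTARP", 7)

# master-equation oracle: adaptive-step ODE integration with deSolve,
# segment by segment, sampled on the same grid as simulate_protocol()
ode_oracle <- function(scheme, protocol, initial = "equilibrium") {
  seg <- protocol$segments
  m <- nrow(seg)
  edges <- cumsum(seg$duration)
  starts <- c(0, edges[-m])
  dt <- protocol$dt
  tgrid <- seq(0, edges[m] + dt * 1e-9, by = dt)
  p <- if (identical(initial, "equilibrium"))
    equilibrium_occupancy(scheme, seg$concentration[1]) else initial
  occ <- matrix(NA_real_, length(tgrid), length(p))
  occ[1, ] <- p
  for (j in seq_len(m)) {
    Qt <- t(generator_matrix(scheme, seg$concentration[j]))
    idx <- which(tgrid > starts[j] + dt * 1e-6 &
                   tgrid <= edges[j] + dt * 1e-6)
    times <- c(0, tgrid[idx] - starts[j], seg$duration[j])
    sol <- deSolve::lsoda(
      y = p, times = sort(unique(times)),
      func = function(t, y, parms) list(Qt %*% y),
      rtol = 1e-10, atol = 1e-12)
    sol_t <- sol[, 1]
    if (length(idx))
      occ[idx, ] <- sol[match(signif(tgrid[idx] - starts[j], 10),
                              signif(sol_t, 10)), -1]
    p <- sol[nrow(sol), -1]
  }
  occ
}
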