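#' Multi-exponential relaxation fit
#'
#' Least-squares fit of `y(t) = baseline + sum_i a_i exp(-k_i (t - t0))`
#' to a current segment, the standard analysis for desensitization and
#' deactivation decays (two components) and CTZ superactivation rises.
#' Rates are optimized on a log scale from a fixed multi-start grid
#' (deterministic: repeated calls are bit-identical); amplitudes and
#' baseline are solved linearly at each rate guess, and the best start is
#' polished with Levenberg-Marquardt.
#'
#' @param time,current Numeric vectors (s; normalized current).
#' @param window Optional `c(from, to)` restricting the fit (defaults to
#'   the full series).  `t0` is the window start.
#' @param n_components Number of exponential components (1--3).
#' @param baseline `"free"` (fitted) or `"zero"` (fixed at 0).
#' @return An object of class `exp_fit`: list with `amplitudes`, `rates`
#'   (s^-1, sorted decreasing), `weighted_rate` (amplitude-weighted mean
#'   rate, `sum(|a| k)/sum(|a|)`), `baseline`, `fitted`, `residual_norm`,
#'   `time` (the fitted time points) and `converged`.
#' @export
#' @examples
#' t <- seq(0, 0.1, 5e-5)
#' y <- 0.7 * exp(-100 * t) + 0.3 * exp(-10 * t)
#' f <- fit_exponentials(t, y, n_components = 2)
#' f$rates          # ~ c(100, 10)
#' f$weighted_rate  # ~ 73
fit_exponentials <- function(time, current, window = NULL,
                             n_components = 2,
                             baseline = c("free", "zero")) {
  baseline <- match.arg(baseline)
  stopifnot(length(time) == length(current),
            n_components %in% 1:3)
  if (!is.null(window)) {
    keep <- time >= window[1] & time <= window[2]
    time <- time[keep]; current <- current[keep]
  }
  if (length(time) < 10 * n_components)
    stop("fit window must contain at least ", 10 * n_components,
         " samples", call. = FALSE)
  t0 <- time[1]
  tt <- time - t0
  span <- max(tt)

  # linear solve for amplitudes/baseline at fixed rates
  design <- function(k) {
    X <- vapply(k, function(ki) exp(-ki * tt), numeric(length(tt)))
    if (baseline == "free") X <- cbind(X, 1)
    X
  }
  sse_at <- function(k) {
    X <- design(k)
    fit <- stats::lm.fit(X, current)
    sum(fit$residuals^2)
  }

  # deterministic multi-start grid over log-spaced rates
  grid <- exp(seq(log(0.5 / span), log(2 / (tt[2] - tt[1])),
                  length.out = 9))
  combos <- switch(n_components,
    `1` = matrix(grid, ncol = 1),
    `2` = {
      cc <- expand.grid(k1 = grid, k2 = grid)
      as.matrix(cc[cc$k1 > 2 * cc$k2, ])
    },
    `3` = {
      cc <- expand.grid(k1 = grid, k2 = grid, k3 = grid)
      as.matrix(cc[cc$k1 > 2 * cc$k2 & cc$k2 > 2 * cc$k3, ])
    })
  sses <- apply(combos, 1, sse_at)
  k_start <- sort(combos[which.min(sses), ], decreasing = TRUE)

  # rates parameterized as a slowest rate plus log-ratios >= 2 between
  # successive components, which excludes degenerate equal-rate pairs
  to_k <- function(p) {
    k <- exp(p[1])
    if (length(p) > 1)
      k <- c(k, k[1] * cumprod(2 + exp(p[-1])))
    sort(k, decreasing = TRUE)
  }
  p0 <- c(log(min(k_start)),
          if (n_components > 1)
            log(pmax(rev(k_start)[-1] / rev(k_start)[-n_components] - 2,
                     0.5)))
  resid_fun <- function(p) {
    X <- design(to_k(p))
    stats::lm.fit(X, current)$residuals
  }
  nls_fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, fn = resid_fun,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(nls_fit))
    stop("multi-exponential fit failed to converge from the multi-start ",
         "grid", call. = FALSE)
  k <- to_k(nls_fit$par)
  X <- design(k)
  lin <- stats::lm.fit(X, current)
  a <- lin$coefficients[seq_along(k)]
  b <- if (baseline == "free") lin$coefficients[length(k) + 1] else 0
  ord <- order(k, decreasing = TRUE)
  k <- unname(k[ord]); a <- unname(a[ord])
  # the weighted mean rate is taken over the components that share the
  # sign of the dominant one: small opposite-sign terms are rounding
  # transients (e.g. the sub-sample rise at a concentration step), not
  # relaxation components
  dom <- sign(a[which.max(abs(a))])
  w <- ifelse(sign(a) == dom, abs(a), 0)
  structure(
    list(amplitudes = a, rates = k,
         weighted_rate = sum(w * k) / sum(w),
         baseline = unname(b),
         fitted = as.numeric(X %*% lin$coefficients),
         residual_norm = sqrt(sum(lin$residuals^2)),
         time = time, converged = nls_fit$info %in% 1:4),
    class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat("Exponential fit:", length(x$rates), "component(s)\n")
  for (i in seq_along(x$rates))
    cat(sprintf("  a%d = %+.4g   k%d = %.4g s^-1\n", i, x$amplitudes[i],
                i, x$rates[i]))
  cat(sprintf("  baseline = %.4g; weighted rate = %.4g s^-1\n",
              x$baseline, x$weighted_rate))
  invisible(x)
}

#' Fit a two-pulse recovery curve
#'
#' Fits the fractional test-pulse response against the inter-pulse
#' interval with a Hodgkin-Huxley-type recovery function
#' `N(t) = N0 + (1 - N0) (1 - exp(-k_rec t))^m`,
#' where `N0` is the active fraction at the end of the conditioning pulse
#' and `k_rec` the recovery rate.  The default exponent is `m = 1` (a
#' single resetting step, matching this scheme's one rate-limiting exit
#' from desensitization, and the exact nested limit of the suprarecovery
#' model); the conventional squared form is available via `exponent = 2`.
#'
#' @param intervals Inter-pulse intervals (s), >= 4 points.
#' @param responses Fractional responses (test peak / conditioning peak).
#' @param exponent HH exponent `m` (default 1).
#' @return Object of class `recovery_fit`: list with `k_rec`, `N0`,
#'   `model` (`"HH"`), `exponent`, `fitted`, `residual_norm`,
#'   `overshoot` (logical: any response exceeded 1 by more than 2%, in
#'   which case [fit_suprarecovery()] is the appropriate model).
#' @export
#' @examples
#' iv <- c(0.005, 0.01, 0.02, 0.05, 0.1, 0.2, 0.5)
#' fit_recovery(iv, 0.2 + 0.8 * (1 - exp(-20 * iv)))$k_rec  # 20
fit_recovery <- function(intervals, responses, exponent = 1) {
  stopifnot(length(intervals) == length(responses))
  if (length(intervals) < 4)
    stop("need at least 4 recovery points", call. = FALSE)
  if (any(responses <= 0))
    stop("responses must be positive", call. = FALSE)
  if (stats::sd(responses) < 1e-10 || all(abs(responses - 1) < 1e-6))
    stop("responses are degenerate (all fully recovered); k_rec is ",
         "unidentifiable", call. = FALSE)
  overshoot <- any(responses > 1.02)
  model_fun <- function(p) {
    k <- exp(p[1]); n0 <- stats::plogis(p[2])
    n0 + (1 - n0) * (1 - exp(-k * intervals))^exponent
  }
  best <- NULL
  for (k0 in c(2, 10, 30, 100, 300)) {
    fit <- tryCatch(minpack.lm::nls.lm(
      par = c(log(k0), stats::qlogis(min(max(min(responses), 1e-3),
                                         1 - 1e-3))),
      fn = function(p) responses - model_fun(p),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best))
    stop("recovery fit did not converge", call. = FALSE)
  structure(
    list(k_rec = exp(best$par[1]), N0 = stats::plogis(best$par[2]),
         N_sup = NA_real_, k_sup = NA_real_,
         model = "HH", exponent = exponent,
         fitted = model_fun(best$par),
         residual_norm = sqrt(best$deviance),
         overshoot = overshoot),
    class = "recovery_fit")
}

#' Fit a recovery curve showing suprarecovery
#'
#' Sum-of-two-exponentials recovery model for curves that overshoot full
#' recovery: a rising recovery component and a decaying superactivation
#' component,
#' `N(t) = 1 + N_sup exp(-k_sup t) - (1 - N0 + N_sup) exp(-k_rec t)`,
#' constrained to `N(0) = N0` and `N(inf) = 1`.  `N_sup` is the amplitude
#' of superactivation and `k_sup` its rate of dissipation.
#'
#' @param intervals Inter-pulse intervals (s), >= 6 points.
#' @param responses Fractional responses; at least one should exceed 1
#'   (otherwise the fit falls back to [fit_recovery()] and flags it).
#' @return Object of class `recovery_fit` with `k_rec`, `N0`, `N_sup`,
#'   `k_sup`, `model = "biexponential"`, plus `fallback = TRUE` when no
#'   overshoot was present and a plain recovery fit was returned.
#' @export
fit_suprarecovery <- function(intervals, responses) {
  stopifnot(length(intervals) == length(responses))
  if (length(intervals) < 6)
    stop("need at least 6 recovery points", call. = FALSE)
  if (!any(responses > 1)) {
    out <- fit_recovery(intervals, responses)
    out$fallback <- TRUE
    return(out)
  }
  model_fun <- function(p) {
    krec <- exp(p[1]); n0 <- stats::plogis(p[2])
    nsup <- exp(p[3]); ksup <- exp(p[4])
    1 + nsup * exp(-ksup * intervals) -
      (1 - n0 + nsup) * exp(-krec * intervals)
  }
  n0_start <- min(max(min(responses), 1e-3), 1 - 1e-3)
  nsup_start <- max(max(responses) - 1, 0.01)
  best <- NULL
  for (k0 in c(5, 15, 40, 120)) for (ks in c(0.5, 1.5, 4)) {
    fit <- tryCatch(minpack.lm::nls.lm(
      par = c(log(k0), stats::qlogis(n0_start), log(nsup_start), log(ks)),
      fn = function(p) responses - model_fun(p),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best))
    stop("suprarecovery fit did not converge", call. = FALSE)
  structure(
    list(k_rec = exp(best$par[1]), N0 = stats::plogis(best$par[2]),
         N_sup = exp(best$par[3]), k_sup = exp(best$par[4]),
         model = "biexponential", exponent = NA,
         fitted = model_fun(best$par),
         residual_norm = sqrt(best$deviance),
         overshoot = TRUE, fallback = FALSE),
    class = "recovery_fit")
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat("Recovery fit [", x$model, "]: k_rec =", format(x$k_rec, digits = 4),
      "s^-1, N0 =", format(x$N0, digits = 3))
  if (x$model == "biexponential")
    cat(", N_sup =", format(x$N_sup, digits = 3),
        ", k_sup =", format(x$k_sup, digits = 4), "s^-1")
  cat("\n")
  invisible(x)
}

#' Hill fit of a concentration-response relation
#'
#' Fits `y(c) = y_max c^h / (c^h + EC50^h)` by Levenberg-Marquardt from a
#' deterministic multi-start grid.
#'
#' @param concentrations Agonist concentrations (M), >= 5 values spanning
#'   the EC50.
#' @param responses Peak or steady-state responses.
#' @return List with `ec50` (M), `hill` (slope), `ymax`, `fitted`,
#'   `residual_norm`.
#' @export
fit_hill <- function(concentrations, responses) {
  stopifnot(length(concentrations) == length(responses))
  if (length(concentrations) < 5)
    stop("need at least 5 concentrations", call. = FALSE)
  if (stats::sd(responses) < 1e-12 * max(abs(responses)))
    stop("responses do not vary with concentration; Hill fit is ",
         "unidentifiable", call. = FALSE)
  model_fun <- function(p) {
    ec <- exp(p[1]); h <- exp(p[2]); ym <- p[3]
    ym * concentrations^h / (concentrations^h + ec^h)
  }
  best <- NULL
  for (ec0 in stats::quantile(concentrations, c(0.25, 0.5, 0.75)))
    for (h0 in c(0.8, 1, 1.5)) {
      fit <- tryCatch(minpack.lm::nls.lm(
        par = c(log(ec0), log(h0), max(responses)),
        fn = function(p) responses - model_fun(p),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit) &&
          (is.null(best) || fit$deviance < best$deviance)) best <- fit
    }
  if (is.null(best)) stop("Hill fit did not converge", call. = FALSE)
  list(ec50 = exp(best$par[1]), hill = exp(best$par[2]),
       ymax = best$par[3], fitted = model_fun(best$par),
       residual_norm = sqrt(best$deviance))
}
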