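#' Known scheme variants
#'
#' @return Character vector of the variant tags accepted by
#'   [build_scheme()].
#' @export
scheme_variants <- function() {
  c("noTARP", "TARP", "TARP+CTZ", "noTARP+CTZ",
    "kainate", "kainate-noTARP",
    "alt-binding", "alt-equal-conductance")
}

# Single-layer state/transition tables.  `suffix`/`Suffix` decorate the
# state names for the two-layer schemes; rate-name substitutions let the
# TARP-active layer swap beta -> beta_s, d2 -> d2*, and (alt-binding only)
# k- -> k*-, kd- -> kd*-.
layer_states <- function(names, layer, g_open) {
  data.frame(
    name        = names,
    layer       = layer,
    class       = c("resting", "bound", "open",
                    "desensitized", "desensitized", "desensitized"),
    conductance = c(0, 0, g_open, 0, 0, 0))
}

layer_transitions <- function(nm, beta = "beta", d2p = "d2+", d2m = "d2-",
                              km = "k-", kdm = "kd-", alpha = "alpha") {
  # nm: the six state names in order R, AR, AR*, AD1, AD2, AD0
  data.frame(
    from = nm[c(1, 2, 2, 4, 2, 4)],
    to   = nm[c(2, 3, 4, 5, 6, 1)],
    fwd  = c("k+", beta, "d1+", d2p, "d0+", kdm),
    bwd  = c(km, alpha, "d1-", d2m, "d0-", "k+"))
}

rung_transitions <- function(basal, active, fwd_names) {
  # the open pair uses its own TARP activation/deactivation rates
  data.frame(from = basal, to = active, fwd = fwd_names,
             bwd = ifelse(fwd_names == "s*+", "s*-", "s-"))
}

#' Build a kinetic scheme
#'
#' Constructs the executable form of a gating scheme for AMPA receptors
#' with or without TARPs, as a state graph with reversible transitions
#' referencing named rate constants.
#'
#' The single-layer (`"noTARP"`) scheme has six states: resting `R`,
#' bound-closed `AR`, open `AR*`, the main desensitized chain `AD1` and
#' `AD2`, and a shallow desensitized state `AD0`.  Topology: `R - AR`
#' (agonist binding, `k+` times concentration / `k-`), `AR - AR*`
#' (`beta`/`alpha`), `AR - AD1` (`d1+`/`d1-`), `AD1 - AD2` (`d2+`/`d2-`),
#' `AR - AD0` (`d0+`/`d0-`), and `AD1 - R` (agonist unbinding from the
#' desensitized receptor, `kd-` forward, `k+` times concentration
#' backward).  Two placements matter and are chosen on kinetic grounds:
#' the desensitized unbinding exit returns directly to `R`, so exit from
#' desensitization is rate-limited by the lifetime of the deep
#' desensitized state (`d2-`) -- the quantity the mutant series varies --
#' rather than by a slowly-emptying unliganded reservoir; and the shallow
#' `d0` branch hangs off the bound state, where its slow entry (1 s^-1)
#' is a minor desensitization pathway, rather than off `R`, where the
#' printed rates would park a quarter of all receptors in a slowly
#' exchanging resting pool that distorts every two-pulse and train
#' protocol.
#'
#' The two-layer (`"TARP"`) scheme duplicates this topology: a basal layer
#' (lower-case `s` in state names; the TARP has no kinetic influence) and
#' a TARP-active layer (upper-case `S`) in which the opening rate is
#' `beta_s` instead of `beta` and the deep desensitized exit/entry use
#' `d2*+`/`d2*-`.  All other within-layer rates are shared.  The layers
#' are connected on every state pair: by `s+`/`s-` on the closed pairs
#' (the rung out of the deep desensitized pair gets its own name `s2+`,
#' the dependent rate that closes that cycle) and by `s*+`/`s*-` on the
#' open pair.  Because opening is far more efficacious in the active
#' layer, closing the open-state cycle forces `s*+ >> s+`: channel
#' opening promotes the TARP into its active state, the source of
#' superactivation.
#'
#' Variants:
#' \describe{
#'   \item{`"TARP+CTZ"`, `"noTARP+CTZ"`}{cyclothiazide block of
#'     desensitization: `d0+`, `d1+` (and `d2*+` where present) set to
#'     0.1 s^-1.  Set `ctz_d2 = TRUE` to also reduce the basal `d2+`.}
#'   \item{`"kainate"`, `"kainate-noTARP"`}{partial-agonist rate set
#'     ([kainate_rates()]); basal open conductance 0.08.}
#'   \item{`"alt-binding"`}{alternate hypothesis: TARPs slow agonist
#'     unbinding (active-layer `k*-` = `k-` / `alt_unbinding_factor`,
#'     `kd*-` analogous) instead of boosting opening (`beta_s` is set
#'     equal to `beta`).  The rungs on the bound and desensitized pairs
#'     get their own dependent names so the scheme can be balanced.}
#'   \item{`"alt-equal-conductance"`}{as `"TARP"` but the active-layer
#'     open state has the same conductance as the basal one.}
#' }
#'
#' Open-state conductances are normalized: basal `AR(s)*` 0.4, active
#' `ARS*` 1.0 (2.5-fold higher), kainate basal 0.08.
#'
#' Schemes are built with the printed rates and are generally *not*
#' balanced: call [enforce_microscopic_reversibility()] before simulating,
#' or use [build_trial_scheme()] which does both.
#'
#' @param variant One of [scheme_variants()].
#' @param rates Named rate vector; defaults to [default_rates()]
#'   ([kainate_rates()] for the kainate variants).
#' @param ctz_d2 Logical; for the CTZ variants also set the basal `d2+`
#'   to 0.1 s^-1 (off by default: the published modification leaves it).
#' @param alt_unbinding_factor Fold reduction of active-layer unbinding
#'   in the `"alt-binding"` variant (default 10).
#' @return An object of class `kinetic_scheme`: a list with elements
#'   `states` (data frame: `name`, `layer`, `class`, `conductance`),
#'   `transitions` (data frame: `from`, `to`, `fwd`, `bwd` rate names),
#'   `rates` (named numeric), `variant`, `balanced` (logical) and
#'   `dependent_rates` (rate names free to move when balancing).
#' @export
#' @examples
#' sch <- build_scheme("TARP")
#' nrow(sch$states)                      # 12 states
#' sum(sch$states$conductance > 0)       # 2 open states
build_scheme <- function(variant, rates = NULL, ctz_d2 = FALSE,
                         alt_unbinding_factor = 10) {
  variant <- match.arg(variant, scheme_variants())
  kainate <- variant %in% c("kainate", "kainate-noTARP")
  if (is.null(rates))
    rates <- if (kainate) kainate_rates() else default_rates()
  required <- names(default_rates())
  missing <- setdiff(required, names(rates))
  if (length(missing))
    stop("missing rate name(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- !is.finite(rates) | rates <= 0
  if (any(bad))
    stop("all rates must be strictly positive; offending: ",
         paste(names(rates)[bad], collapse = ", "), call. = FALSE)

  two_layer <- !variant %in% c("noTARP", "noTARP+CTZ", "kainate-noTARP")
  g_basal <- if (kainate) 0.08 else 0.4
  g_active <- if (variant == "alt-equal-conductance") g_basal else 1.0

  if (variant %in% c("TARP+CTZ", "noTARP+CTZ")) {
    rates[["d0+"]] <- 0.1
    rates[["d1+"]] <- 0.1
    if (two_layer) rates[["d2*+"]] <- 0.1
    if (ctz_d2) rates[["d2+"]] <- 0.1
  }

  if (!two_layer) {
    nm <- c("R", "AR", "AR*", "AD1", "AD2", "AD0")
    states <- layer_states(nm, "s", g_basal)
    trans <- layer_transitions(nm)
    dep <- "kd-"
  } else {
    lo <- c("Rs", "ARs", "ARs*", "ADs1", "ADs2", "AD0s")
    hi <- c("RS", "ARS", "ARS*", "ADS1", "ADS2", "AD0S")
    states <- rbind(layer_states(lo, "s", g_basal),
                    layer_states(hi, "S", g_active))
    rates[["alpha_s"]] <- rates[["alpha"]]
    if (variant == "alt-binding") {
      rates[["beta_s"]] <- rates[["beta"]]
      rates[["k*-"]] <- rates[["k-"]] / alt_unbinding_factor
      rates[["kd*-"]] <- rates[["kd-"]] / alt_unbinding_factor
      active <- layer_transitions(hi, beta = "beta_s", d2p = "d2*+",
                                  d2m = "d2*-", km = "k*-", kdm = "kd*-",
                                  alpha = "alpha_s")
      rates[["sb+"]] <- rates[["sd1+"]] <- rates[["s+"]]
      rungs <- rung_transitions(lo, hi,
        c("s+", "sb+", "s*+", "sd1+", "s2+", "sb+"))
      dep <- c("s*+", "s2+", "kd-", "sb+", "sd1+", "kd*-")
    } else {
      active <- layer_transitions(hi, beta = "beta_s", d2p = "d2*+",
                                  d2m = "d2*-", alpha = "alpha_s")
      rungs <- rung_transitions(lo, hi,
        c("s+", "s+", "s*+", "s+", "s2+", "s+"))
      dep <- c("s*+", "s2+", "kd-")
    }
    rates[["s2+"]] <- rates[["s+"]]
    trans <- rbind(layer_transitions(lo), active, rungs)
  }

  structure(
    list(states = states, transitions = trans, rates = rates,
         variant = variant, trial = NA_integer_, balanced = FALSE,
         dependent_rates = dep),
    class = "kinetic_scheme")
}

#' Build, parameterize and balance a scheme in one call
#'
#' Convenience wrapper: [build_scheme()], then [apply_mutant_trial()],
#' then [enforce_microscopic_reversibility()].
#'
#' @inheritParams build_scheme
#' @param trial Mutant-series trial id (0--8) or `NULL` to keep the
#'   baseline `d2-`/`d2*-`.
#' @param ... Passed to [build_scheme()].
#' @return A balanced `kinetic_scheme`.
#' @export
#' @examples
#' wt <- build_trial_scheme("TARP", trial = 7)  # wild-type proxy
#' wt$balanced
build_trial_scheme <- function(variant, trial = NULL, rates = NULL, ...) {
  sch <- build_scheme(variant, rates = rates, ...)
  if (!is.null(trial)) sch <- apply_mutant_trial(sch, trial)
  enforce_microscopic_reversibility(sch)
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Kinetic scheme [", x$variant, "]",
      if (!is.na(x$trial)) paste0(" trial ", x$trial), "\n", sep = "")
  cat(" ", nrow(x$states), "states,", nrow(x$transitions),
      "reversible transitions;",
      if (x$balanced) "balanced" else "NOT balanced (printed rates)", "\n")
  op <- x$states[x$states$conductance > 0, ]
  cat("  open states:",
      paste(sprintf("%s (g=%g)", op$name, op$conductance), collapse = ", "),
      "\n")
  invisible(x)
}

#' Generator (Q) matrix of a scheme at a given agonist concentration
#'
#' Assembles the infinitesimal generator of the continuous-time Markov
#' chain: off-diagonal `Q[i, j]` is the rate of the `i -> j` transition
#' (entries whose rate name is `k+` are multiplied by the concentration),
#' and each diagonal entry is minus the row sum, so rows sum to zero.
#'
#' @param scheme A `kinetic_scheme`.
#' @param concentration Agonist concentration in molar (>= 0).
#' @return Square numeric matrix (s^-1) with state names as dimnames.
#' @export
#' @examples
#' Q <- generator_matrix(build_scheme("noTARP"), 0.01)
#' Q["R", "AR"]   # k+ * 0.01 = 50,000 s^-1
generator_matrix <- function(scheme, concentration) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (!is.numeric(concentration) || length(concentration) != 1 ||
      is.na(concentration) || concentration < 0)
    stop("concentration must be a single non-negative number (molar)",
         call. = FALSE)
  nm <- scheme$states$name
  n <- length(nm)
  Q <- matrix(0, n, n, dimnames = list(nm, nm))
  r <- scheme$rates
  tr <- scheme$transitions
  scale_rate <- function(rate_name)
    unname(r[[rate_name]]) * if (rate_name == "k+") concentration else 1
  for (i in seq_len(nrow(tr))) {
    Q[tr$from[i], tr$to[i]] <- Q[tr$from[i], tr$to[i]] + scale_rate(tr$fwd[i])
    Q[tr$to[i], tr$from[i]] <- Q[tr$to[i], tr$from[i]] + scale_rate(tr$bwd[i])
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Equilibrium (stationary) state occupancy
#'
#' Computes the stationary distribution of the generator matrix at a fixed
#' agonist concentration, i.e. the probability vector `p` with
#' `t(Q) p = 0`, `sum(p) = 1`, via the null space of `t(Q)` (SVD).  For a
#' balanced scheme this distribution also satisfies detailed balance on
#' every transition.
#'
#' @inheritParams generator_matrix
#' @return Named probability vector over states.
#' @export
#' @examples
#' p0 <- equilibrium_occupancy(build_trial_scheme("TARP", 7), 0)
#' p0[["RS"]]   # basally superactive fraction, ~0.065
equilibrium_occupancy <- function(scheme, concentration) {
  Q <- generator_matrix(scheme, concentration)
  sv <- svd(t(Q))
  d <- sv$d
  scale <- max(d)
  if (d[length(d) - 1L] / scale < 1e-9)
    stop("stationary distribution is not unique (disconnected scheme?)",
         call. = FALSE)
  if (d[length(d)] / scale > 1e-7)
    stop("generator has no numerical null space; matrix looks singular ",
         "beyond tolerance", call. = FALSE)
  p <- sv$v[, length(d)]
  p <- p / sum(p)
  if (min(p) < -1e-9)
    stop("stationary vector has negative entries beyond tolerance",
         call. = FALSE)
  p[p < 0] <- 0
  p <- p / sum(p)
  names(p) <- scheme$states$name
  p
}
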