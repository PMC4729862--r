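#' Default rate constants for the AMPAR / AMPAR-TARP gating schemes
#'
#' Returns the published baseline rate set for the single-binding-site
#' gating scheme and its two-layer TARP extension, before any
#' microscopic-reversibility adjustment.  All rates are in s^-1 except the
#' agonist association rate `k+`, which is in M^-1 s^-1 and is multiplied
#' by the agonist concentration wherever it appears in a scheme.
#'
#' Rate names follow the field notation:
#' \describe{
#'   \item{`k+`, `k-`}{agonist binding / unbinding on the resting receptor}
#'   \item{`beta`, `alpha`}{channel opening / shutting (basal TARP layer)}
#'   \item{`beta_s`}{boosted opening rate in the TARP-active layer.  The
#'     active layer's shutting rate `alpha_s` is created at scheme build
#'     time, initialized to `alpha`, and held at that baseline across the
#'     mutant series (the superactive complex's shutting is a property of
#'     the TARP interaction, not of the mutated binding domain)}
#'   \item{`d1+`, `d1-`}{entry to / exit from the proximal desensitized
#'     state AD1}
#'   \item{`d2+`, `d2-`}{entry to / exit from the deep desensitized state
#'     AD2 (basal layer); `d2*+`, `d2*-` are the TARP-active counterparts}
#'   \item{`d0+`, `d0-`}{entry to / exit from the shallow desensitized
#'     state AD0 (off the bound-closed state)}
#'   \item{`kd-`}{agonist unbinding from the desensitized receptor
#'     (AD1 to R)}
#'   \item{`s+`, `s-`}{TARP activation / deactivation on closed states}
#'   \item{`s*+`, `s*-`}{TARP activation / deactivation on the open state}
#' }
#'
#' @return Named numeric vector of 18 rate constants.
#' @seealso [build_scheme()], [kainate_rates()], [mutant_trials()]
#' @export
#' @examples
#' default_rates()[["beta"]]   # basal opening rate, s^-1
default_rates <- function() {
  c(`s*+`  = 15,
    `s*-`  = 3,
    `s+`   = 0.07,
    `s-`   = 1,
    beta   = 8000,
    alpha  = 3000,
    beta_s = 500000,
    `d2*+` = 120,
    `d2*-` = 2,
    `d2+`  = 120,
    `d2-`  = 5,
    `d1+`  = 300,
    `d1-`  = 25,
    `d0+`  = 1,
    `d0-`  = 3,
    `k+`   = 5e6,
    `k-`   = 40000,
    `kd-`  = 2500)
}

#' Rate constants for activation by kainate
#'
#' Kainate is a weak partial agonist of AMPA receptors.  Relative to the
#' glutamate rate set ([default_rates()]) the opening rate is reduced
#' 5-fold, shutting is much faster, desensitization is slower and
#' shallower, and the boosted opening rate of the TARP-active layer is
#' reduced by the same factor as the basal one, preserving the strength of
#' the receptor-TARP coupling.
#'
#' @return Named numeric vector with the kainate overrides applied:
#'   `beta` = 1,600; `alpha` = 30,000; `d2+` = 12; `d2-` = 30;
#'   `d2*-` = 12; `d1-` = 300; `beta_s` = 100,000.
#' @export
kainate_rates <- function() {
  r <- default_rates()
  r[["beta"]]   <- 1600
  r[["alpha"]]  <- 30000
  r[["d2+"]]    <- 12
  r[["d2-"]]    <- 30
  r[["d2*-"]]   <- 12
  r[["d1-"]]    <- 300
  r[["beta_s"]] <- 100000
  r
}

#' Mutant-series trial rates
#'
#' The kinetic diversity of a panel of ligand-binding-domain mutants is
#' captured by varying the lifetime of the deep desensitized state -- the
#' exit rates `d2-` (basal layer) and `d2*-` (TARP-active layer) -- with
#' a compensating modest alteration of the basal channel shutting rate
#' `alpha`, consistent with the slower deactivation of slow-recovering
#' mutants.  Trial 0 represents a slow-recovering mutant (e.g. GluA2
#' E713T/Y768R), trial 8 a fast-recovering one (e.g. GluA2 K761M), and
#' trial 7 is the closest approximation to wild-type GluA2.
#'
#' The per-trial `alpha` is anchored to published deactivation
#' phenotypes: ~270 s^-1 for the slow double mutant, ~1,000 s^-1 for
#' wild type, and ~3,100 s^-1 for the fast mutant.  `alpha` scales those
#' ratios from the baseline 3,000 s^-1 (trial 7), log-interpolated along
#' `d2-` for intermediate trials.  In the two-layer scheme the
#' TARP-active layer's shutting rate (`alpha_s`) is *not* altered by the
#' mutation; re-balancing then makes the TARP activation rate `s*+` rise
#' in proportion to `alpha`, so receptors with lower gating efficacy
#' activate their TARPs more readily -- the source of the predicted
#' correlation between recovery rate and steady-state boost.
#'
#' @return A data frame with columns `trial` (integer 0--8), `d2_minus`,
#'   `d2star_minus`, and `alpha` (all s^-1).
#' @seealso [apply_mutant_trial()]
#' @export
mutant_trials <- function() {
  d2m <- c(0.16, 0.32, 0.63, 1.26, 2.51, 5.0, 10.0, 19.9, 39.7)
  # deactivation ratios to wild type: 270/1000 at trial 0, 1 at trial 7,
  # 3100/1000 at trial 8; log-linear in log(d2-) between anchors
  lr <- stats::approx(x = log(c(0.16, 19.9, 39.7)),
                      y = log(c(0.27, 1, 3.1)),
                      xout = log(d2m))$y
  data.frame(
    trial        = 0:8,
    d2_minus     = d2m,
    d2star_minus = c(0.18, 0.29, 0.47, 0.76, 1.23, 2.0, 3.24, 5.26, 8.53),
    alpha        = 3000 * exp(lr))
}

#' Substitute the mutant-trial rates into a scheme
#'
#' Replaces `d2-` and `d2*-` (and, unless `vary_alpha = FALSE`, the basal
#' shutting rate `alpha`) with the values of one row of the mutant series
#' ([mutant_trials()]).  The TARP-active layer's shutting rate `alpha_s`
#' is left at its baseline.  The balanced flag is cleared: the caller
#' must re-run [enforce_microscopic_reversibility()], which compensates
#' the altered rates by recomputing the dependent TARP activation rate
#' `s*+` (and the desensitized-pair rung `s2+`).
#'
#' @param scheme A [kinetic_scheme][build_scheme] object.
#' @param trial Integer trial id in 0--8, or a single-row data frame with
#'   columns `d2_minus`, `d2star_minus` and optionally `alpha`.
#' @param vary_alpha Apply the per-trial basal `alpha` (default `TRUE`).
#' @return The scheme with substituted rates and `balanced = FALSE`.
#' @export
apply_mutant_trial <- function(scheme, trial, vary_alpha = TRUE) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (is.data.frame(trial)) {
    row <- trial
  } else {
    if (!is.numeric(trial) || length(trial) != 1 || !trial %in% 0:8)
      stop("trial id must be a single integer in 0..8", call. = FALSE)
    row <- mutant_trials()[mutant_trials()$trial == trial, ]
  }
  scheme$rates[["d2-"]] <- row$d2_minus
  if ("d2*-" %in% names(scheme$rates))
    scheme$rates[["d2*-"]] <- row$d2star_minus
  if (vary_alpha && !is.null(row$alpha))
    scheme$rates[["alpha"]] <- row$alpha
  scheme$balanced <- FALSE
  scheme$trial <- if (is.data.frame(trial)) row$trial else as.integer(trial)
  scheme
}
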