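# Fundamental-cycle machinery.  The state graph is undirected (every
# transition is reversible); a spanning tree is taken and each non-tree
# edge closes exactly one fundamental cycle.  Cycle products are evaluated
# at unit concentration: in any physical cycle the agonist-binding steps
# appear equally often in both directions, so the concentration cancels.

fundamental_cycles <- function(scheme) {
  tr <- scheme$transitions
  g <- igraph::graph_from_data_frame(tr[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = scheme$states$name)
  if (igraph::components(g)$no != 1L)
    stop("scheme state graph is not connected", call. = FALSE)
  tree <- igraph::mst(g)
  edge_key <- function(ends)
    paste(pmin(ends[, 1], ends[, 2]), pmax(ends[, 1], ends[, 2]), sep = "|")
  g_ends <- igraph::as_edgelist(g)
  tree_keys <- edge_key(igraph::as_edgelist(tree))
  # schemes have no parallel edges, so key membership identifies tree edges
  chords <- which(!edge_key(g_ends) %in% tree_keys)
  lapply(chords, function(i) {
    u <- g_ends[i, 1]; v <- g_ends[i, 2]
    path <- igraph::shortest_paths(tree, from = v, to = u)$vpath[[1]]
    # chord u-v plus tree path v..u, without repeating the closing vertex
    utils::head(c(u, names(path)), -1L)
  })
}

# Signed log-rate decomposition of one cycle.  Returns, for each rate name,
# the net exponent with which it appears in the forward/backward product
# ratio, plus the fixed log-imbalance contributed by non-dependent rates.
cycle_terms <- function(scheme, cycle_states) {
  tr <- scheme$transitions
  n <- length(cycle_states)
  terms <- list()
  for (k in seq_len(n)) {
    a <- cycle_states[k]
    b <- cycle_states[if (k == n) 1L else k + 1L]
    hit <- which(tr$from == a & tr$to == b)
    if (length(hit) == 1) {
      fwd <- tr$fwd[hit]; bwd <- tr$bwd[hit]
    } else {
      hit <- which(tr$from == b & tr$to == a)
      if (length(hit) != 1)
        stop("no transition between ", a, " and ", b, call. = FALSE)
      fwd <- tr$bwd[hit]; bwd <- tr$fwd[hit]
    }
    terms[[length(terms) + 1L]] <- c(fwd = fwd, bwd = bwd)
  }
  terms
}

cycle_log_ratio <- function(scheme, cycle_states) {
  terms <- cycle_terms(scheme, cycle_states)
  r <- scheme$rates
  sum(vapply(terms, function(tt) log(r[[tt["fwd"]]]) - log(r[[tt["bwd"]]]),
             numeric(1)))
}

#' Cycle imbalance of a kinetic scheme
#'
#' For every fundamental cycle of the state graph (one per chord of a
#' spanning tree) reports the ratio of the clockwise to counter-clockwise
#' rate products.  The Kolmogorov criterion for microscopic reversibility
#' requires every ratio to equal 1.
#'
#' @param scheme A `kinetic_scheme`.
#' @return Data frame with columns `cycle` (state sequence) and `ratio`;
#'   zero rows for a tree-topology scheme.
#' @seealso [enforce_microscopic_reversibility()]
#' @export
#' @examples
#' cycle_imbalance(build_scheme("TARP"))   # open cycle ratio 8/7 unbalanced
cycle_imbalance <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  cycles <- fundamental_cycles(scheme)
  data.frame(
    cycle = vapply(cycles, paste, character(1), collapse = " -> "),
    ratio = vapply(cycles, function(cy) exp(cycle_log_ratio(scheme, cy)),
                   numeric(1)))
}

#' Enforce microscopic reversibility
#'
#' Recomputes a designated set of dependent forward rates so that every
#' cycle of the scheme satisfies the Kolmogorov criterion (equal forward
#' and backward rate products), leaving all other rates at their printed
#' values.  In log-rate space the cycle conditions are linear in the
#' dependent rates; they are solved by least squares and the result is
#' verified to close every cycle to relative tolerance 1e-10.
#'
#' For the two-layer TARP scheme the defaults are `s*+` (TARP activation
#' on the open pair, the physically meaningful adjustment: opening must
#' promote the TARP towards its active state), `s2+` (the rung out of the
#' deep desensitized pair, whose cycle involves the trial-dependent
#' `d2-`/`d2*-`) and `kd-` (agonist unbinding from the desensitized
#' receptor, closing the within-layer binding/desensitization loop).
#' With the baseline rates the balanced `s*+` is
#' `s+ * beta_s * s*- / (beta * s-)` = 13.125 s^-1 (printed starting
#' value 15).
#'
#' @param scheme A `kinetic_scheme`.
#' @param dependent_rates Character vector of rate names allowed to move;
#'   defaults to `scheme$dependent_rates`.
#' @return The scheme with adjusted rates, `balanced = TRUE`, and an
#'   `adjustment` element: a data frame of (rate, printed, balanced).
#' @export
#' @examples
#' sch <- enforce_microscopic_reversibility(build_scheme("TARP"))
#' sch$adjustment
#' max(abs(cycle_imbalance(sch)$ratio - 1)) < 1e-10
enforce_microscopic_reversibility <- function(scheme,
                                              dependent_rates = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (is.null(dependent_rates)) dependent_rates <- scheme$dependent_rates
  unknown <- setdiff(dependent_rates, names(scheme$rates))
  if (length(unknown))
    stop("dependent rate(s) not in scheme: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  cycles <- fundamental_cycles(scheme)
  if (length(cycles) == 0) {
    scheme$balanced <- TRUE
    scheme$adjustment <- data.frame(rate = character(), printed = numeric(),
                                    balanced = numeric())
    return(scheme)
  }
  r <- scheme$rates
  nd <- length(dependent_rates)
  A <- matrix(0, length(cycles), nd,
              dimnames = list(NULL, dependent_rates))
  b <- numeric(length(cycles))
  for (ci in seq_along(cycles)) {
    terms <- cycle_terms(scheme, cycles[[ci]])
    fixed <- 0
    for (tt in terms) {
      for (side in c(1, -1)) {
        nm <- if (side == 1) tt["fwd"] else tt["bwd"]
        if (nm %in% dependent_rates) {
          A[ci, nm] <- A[ci, nm] + side
        } else {
          fixed <- fixed + side * log(r[[nm]])
        }
      }
    }
    b[ci] <- -fixed
    if (all(A[ci, ] == 0) && abs(fixed) > 1e-10)
      stop("cycle ", paste(cycles[[ci]], collapse = " -> "),
           " is unbalanced but contains no dependent rate", call. = FALSE)
  }
  keep <- colSums(A != 0) > 0
  x <- rep(NA_real_, nd)
  names(x) <- dependent_rates
  if (any(keep)) {
    fit <- qr(A[, keep, drop = FALSE])
    sol <- qr.coef(fit, b)
    sol[is.na(sol)] <- log(r[dependent_rates[keep][is.na(sol)]])
    x[keep] <- sol
  }
  out <- scheme
  changed <- dependent_rates[keep]
  printed <- r[changed]
  out$rates[changed] <- exp(x[changed])
  resid <- vapply(cycles, function(cy) cycle_log_ratio(out, cy), numeric(1))
  if (max(abs(resid)) > 1e-10)
    stop("cycle conditions are inconsistent: a dependent rate is shared ",
         "by cycles with conflicting solutions (max |log ratio| = ",
         format(max(abs(resid))), ")", call. = FALSE)
  out$balanced <- TRUE
  out$adjustment <- data.frame(rate = changed,
                               printed = unname(printed),
                               balanced = unname(out$rates[changed]))
  out
}
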