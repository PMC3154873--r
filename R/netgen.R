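#' Generate a sparse random polynomial dynamical system
#'
#' Fixture factory for solver and scale tests, emulating the structure of
#' biological regulatory networks: many variables, each regulated by only
#' a handful of others. Per-variable in-degrees are drawn from a Poisson
#' distribution truncated to `0..max_in_degree`, with the Poisson rate
#' calibrated (numerically) so the *truncated* mean hits
#' `mean_in_degree`. Each variable then gets a uniformly random update
#' rule over its chosen inputs; rules in which a chosen input turns out
#' non-functional (its variable drops out of the canonical polynomial)
#' are redrawn, so every edge of the generated wiring diagram is
#' functional by construction.
#'
#' @param n number of variables.
#' @param p prime field order (default 2, Boolean).
#' @param mean_in_degree target mean in-degree (default 1.7, the sparse
#'   regime typical of gene regulatory networks).
#' @param max_in_degree per-variable cap on the number of inputs.
#' @param family rule family: `"random-table"` (uniform random truth
#'   table over the inputs), `"conjunctive"` (AND of the inputs), or
#'   `"random-polynomial"` (random coefficients on monomials over the
#'   inputs).
#' @param seed optional integer; identical arguments plus seed reproduce
#'   the system bit for bit.
#' @return A [pds]; attribute `"in_degrees"` records the realized
#'   in-degree of every variable.
#' @export
random_sparse_pds <- function(n, p = 2L, mean_in_degree = 1.7,
                              max_in_degree = 4L,
                              family = c("random-table", "conjunctive",
                                         "random-polynomial"),
                              seed = NULL) {
  family <- match.arg(family)
  p <- as_field_p(p)
  n <- as.integer(n)
  max_in_degree <- min(as.integer(max_in_degree), n)
  if (max_in_degree > n) stop("max_in_degree cannot exceed n")
  if (mean_in_degree < 0) stop("mean_in_degree must be >= 0")
  if (mean_in_degree >= max_in_degree && mean_in_degree > 0) {
    stop("mean_in_degree must be below max_in_degree")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  ks <- 0:max_in_degree
  prob <- if (mean_in_degree == 0) {
    c(1, rep(0, max_in_degree))
  } else {
    lam <- stats::uniroot(function(l) {
      w <- stats::dpois(ks, l)
      sum(ks * w) / sum(w) - mean_in_degree
    }, interval = c(1e-9, 200))$root
    stats::dpois(ks, lam)
  }
  deg <- sample(ks, n, replace = TRUE, prob = prob)

  fns <- vector("list", n)
  for (i in seq_len(n)) {
    k <- deg[[i]]
    if (k == 0L) {
      fns[[i]] <- fp_const(sample(0:(p - 1L), 1L), p, n)
      next
    }
    inputs <- sort(sample.int(n, k))
    for (try in 1:200) {
      f <- switch(family,
        "random-table" = interpolate_table(
          sample(0:(p - 1L), p^k, replace = TRUE), p, n, vars = inputs),
        "conjunctive" = Reduce(fp_mul, lapply(inputs, fp_var, p = p, nvars = n)),
        "random-polynomial" = {
          grid <- all_states(p, k)        # all exponent tuples over the inputs
          expo <- matrix(0L, nrow(grid), n)
          expo[, inputs] <- grid
          fp_make(sample(0:(p - 1L), nrow(grid), replace = TRUE), expo, p, n)
        })
      if (identical(fp_support(f), inputs)) break
      if (try == 200L) stop("failed to draw a rule with all inputs functional")
    }
    fns[[i]] <- f
  }
  out <- pds(fns, p = p)
  attr(out, "in_degrees") <- vapply(out$functions,
                                    function(f) length(fp_support(f)), integer(1))
  out
}

#' Implant prescribed fixed points into a system
#'
#' Minimally edits a system so that each requested state is a fixed
#' point, leaving the rest of the dynamics untouched: for every
#' coordinate, the update rule's *local* truth table (over the
#' variables it depends on) is edited at the rows matching the implanted
#' states only. When two implanted states project to the same local row
#' but demand different outputs, the coordinate's input set is augmented
#' with the fewest extra variables needed to separate them (implanted
#' states are pairwise distinct, so separation always succeeds). At most
#' one local table row changes per implanted state per coordinate. Used
#' as acceptance scaffolding: it plants known fixed points in networks
#' far too large to enumerate, so solver completeness can be checked at
#' scale.
#'
#' @param system a [pds].
#' @param states matrix of states (one per row) or list of state
#'   vectors; must be pairwise distinct.
#' @return A [pds] with `f(s) = s` for every requested `s`.
#' @export
implant_fixed_points <- function(system, states) {
  if (is.list(states)) states <- do.call(rbind, states)
  if (is.null(dim(states))) states <- matrix(states, nrow = 1L)
  storage.mode(states) <- "integer"
  n <- system$nvars
  p <- system$p
  stopifnot(ncol(states) == n)
  keys <- apply(states, 1L, state_to_string)
  if (anyDuplicated(keys)) stop("implanted states must be pairwise distinct")

  fns <- system$functions
  for (i in seq_len(n)) {
    want <- states[, i]
    have <- vapply(seq_len(nrow(states)), function(r) {
      fp_eval(fns[[i]], states[r, ])
    }, integer(1))
    if (all(have == want)) next
    supp <- fp_support(fns[[i]])
    # grow the input set until implanted states needing different
    # outputs occupy different local rows
    repeat {
      projkey <- apply(states[, supp, drop = FALSE], 1L, paste, collapse = ",")
      conflict <- FALSE
      for (g in split(seq_len(nrow(states)), projkey)) {
        if (length(unique(want[g])) > 1L) {
          conflict <- TRUE
          pair <- g[want[g] != want[g[1L]]][1L]
          differ <- which(states[g[1L], ] != states[pair, ])
          supp <- sort(c(supp, setdiff(differ, supp)[1L]))
          break
        }
      }
      if (!conflict) break
    }
    k <- length(supp)
    grid <- all_states(p, k)
    full <- matrix(0L, nrow(grid), n)
    full[, supp] <- grid
    vals <- fp_eval_states(fns[[i]], full)
    rows <- state_index(states[, supp, drop = FALSE], p)
    vals[rows] <- want
    fns[[i]] <- interpolate_table(vals, p, n, vars = supp)
  }
  pds(fns, p = p)
}
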