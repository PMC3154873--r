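#' Solve a system of polynomial equations over F_p
#'
#' Computes the complete set of common roots in F_p^n of a list of
#' polynomial equations (each read as `= 0`). The solver works in the
#' quotient ring by the field equations `x_i^p - x_i`, where every input
#' is already canonical, so the ideal is radical and zero-dimensional and
#' all roots are rational. The engine is exact recursive elimination:
#' unit propagation (constant equations prune, univariate equations
#' restrict a variable to its root set and substitute when the set is a
#' singleton) interleaved with splitting on the most-constrained
#' variable. It never enumerates the `p^n` assignments: only values
#' consistent with the partially propagated system are explored, which is
#' what makes steady-state analysis feasible for networks of a hundred
#' or more variables.
#'
#' @param equations list of [fpoly] over a common ring, each meaning
#'   `poly = 0`.
#' @param p,nvars field and ring; default taken from the first equation.
#' @param solution_limit abort (with an error) if the solution set would
#'   exceed this many states; guards against degenerate systems whose
#'   root set is itself exponential (e.g. the empty system).
#' @return Integer matrix, one solution state per row, sorted by digit
#'   string; zero rows when the system is inconsistent.
#' @examples
#' eq <- parse_polynomial("x1 + x2 + 1", p = 2, nvars = 2)
#' solve_system(list(eq))  # (0,1) and (1,0)
#' @export
solve_system <- function(equations, p = NULL, nvars = NULL,
                         solution_limit = 2^20) {
  stopifnot(is.list(equations))
  if (length(equations) == 0L) {
    if (is.null(p) || is.null(nvars)) {
      stop("empty system needs explicit p and nvars")
    }
  } else {
    if (is.null(p)) p <- equations[[1L]]$p
    if (is.null(nvars)) nvars <- equations[[1L]]$nvars
  }
  p <- as_field_p(p)
  nvars <- as.integer(nvars)
  for (e in equations) {
    if (e$p != p || e$nvars != nvars) stop("equations have inconsistent dimensions")
  }
  eqs <- lapply(equations, canonicalize)
  eqs <- Filter(Negate(fp_is_zero), eqs)

  acc <- new.env(parent = emptyenv())
  acc$sols <- list()
  acc$count <- 0

  # values of a univariate (support {v}) polynomial at 0..p-1
  univ_allowed <- function(f, v) {
    e <- f$expo[, v]
    ok <- integer(0)
    for (val in 0:(p - 1L)) {
      if (sum(f$coef * val^e) %% p == 0L) ok <- c(ok, val)
    }
    ok
  }

  emit <- function(assign) {
    free <- which(is.na(assign))
    nsol <- as.numeric(p)^length(free)
    if (acc$count + nsol > solution_limit) {
      stop("solution set exceeds solution_limit (", solution_limit,
           "); the system is underdetermined at this scale")
    }
    if (length(free) == 0L) {
      acc$sols[[length(acc$sols) + 1L]] <- matrix(assign, nrow = 1L)
    } else {
      grid <- all_states(p, length(free))
      block <- matrix(rep(assign, each = nrow(grid)), nrow(grid), nvars)
      block[, free] <- grid
      acc$sols[[length(acc$sols) + 1L]] <- block
    }
    acc$count <- acc$count + nsol
    invisible(NULL)
  }

  recurse <- function(eqs, assign) {
    # --- propagation ---
    repeat {
      progress <- FALSE
      keep <- rep(TRUE, length(eqs))
      forced_var <- NA_integer_
      forced_val <- NA_integer_
      for (k in seq_along(eqs)) {
        f <- eqs[[k]]
        if (fp_is_zero(f)) { keep[k] <- FALSE; next }
        if (fp_is_constant(f)) return(invisible(NULL))  # nonzero constant: dead branch
        supp <- fp_support(f)
        if (length(supp) == 1L) {
          allowed <- univ_allowed(f, supp)
          if (length(allowed) == 0L) return(invisible(NULL))
          if (length(allowed) == 1L) {
            forced_var <- supp
            forced_val <- allowed
            keep[k] <- FALSE
            break
          }
        }
      }
      eqs <- eqs[keep]
      if (!is.na(forced_var)) {
        assign[forced_var] <- forced_val
        eqs <- lapply(eqs, function(f) {
          if (length(f$coef) && any(f$expo[, forced_var] > 0L)) {
            fp_subst_values(f, forced_var, forced_val)
          } else f
        })
        progress <- TRUE
      }
      if (!progress) break
    }
    if (length(eqs) == 0L) return(emit(assign))

    # --- branch choice ---
    branch_var <- NA_integer_
    branch_vals <- NULL
    for (f in eqs) {            # a univariate equation gives a reduced value set
      supp <- fp_support(f)
      if (length(supp) == 1L) {
        branch_var <- supp
        branch_vals <- univ_allowed(f, supp)
        break
      }
    }
    if (is.na(branch_var)) {    # most frequently occurring variable, lowest index
      counts <- integer(nvars)
      for (f in eqs) {
        s <- fp_support(f)
        counts[s] <- counts[s] + 1L
      }
      branch_var <- which.max(counts)
      branch_vals <- 0:(p - 1L)
    }
    for (val in branch_vals) {
      a2 <- assign
      a2[branch_var] <- val
      e2 <- lapply(eqs, function(f) {
        if (length(f$coef) && any(f$expo[, branch_var] > 0L)) {
          fp_subst_values(f, branch_var, val)
        } else f
      })
      recurse(e2, a2)
    }
    invisible(NULL)
  }

  recurse(eqs, rep(NA_integer_, nvars))
  if (length(acc$sols) == 0L) return(matrix(0L, 0L, nvars))
  out <- do.call(rbind, acc$sols)
  out[order(vapply(asplit(out, 1), state_to_string, character(1))), , drop = FALSE]
}

#' Steady states of a polynomial dynamical system
#'
#' A state is steady (a fixed point) when `f(x) = x`; updating any
#' variable there changes nothing, so the set is the same under
#' synchronous, sequential, or any other update discipline. Computed
#' algebraically by solving `f_i(x) - x_i = 0` for all `i`
#' simultaneously with [solve_system()] — no state-space enumeration, so
#' this scales to large sparse networks.
#'
#' @param system a [pds].
#' @param solution_limit passed to [solve_system()].
#' @return Integer matrix of fixed points, one per row, sorted.
#' @export
steady_states <- function(system, solution_limit = 2^20) {
  n <- system$nvars
  eqs <- lapply(seq_len(n), function(i) {
    fp_sub(system$functions[[i]], fp_var(i, system$p, n))
  })
  solve_system(eqs, p = system$p, nvars = n, solution_limit = solution_limit)
}

# Equations of the length-d orbit unrolling: variables y[t*n + i]
# (t = 0..d-1 blocks), equations f_i(block t) - y[(t+1) mod d, i] = 0.
# Solutions are exactly the tuples (x, f(x), ..., f^(d-1)(x)) with
# f^d(x) = x, so block 0 carries the solutions of f^d(x) = x without
# ever forming the symbolic composition.
unrolled_equations <- function(system, d) {
  n <- system$nvars
  p <- system$p
  total <- n * d
  eqs <- vector("list", total)
  for (t in 0:(d - 1L)) {
    off <- t * n
    nxt <- ((t + 1L) %% d) * n
    for (i in seq_len(n)) {
      f <- system$functions[[i]]
      expo <- matrix(0L, length(f$coef), total)
      if (length(f$coef)) expo[, off + seq_len(n)] <- f$expo
      ft <- fp_make(f$coef, expo, p, total)
      eqs[[off + i]] <- fp_sub(ft, fp_var(nxt + i, p, total))
    }
  }
  eqs
}

#' Attractors of bounded length: steady states and limit cycles
#'
#' States on a cycle of length `m` satisfy `f^m(x) = x`. For each
#' `d = 1..m` the solver finds all solutions of that fixed-point
#' condition — encoded as the unrolled orbit system in `n*d` variables,
#' equivalent to solving `f^d(x) = x` but without symbolic composition —
#' and the solutions are then grouped into orbits by repeatedly applying
#' `f`. Each orbit is reported once with its exact period: period-1
#' orbits as steady states, longer ones as cycles printed from their
#' lexicographically smallest state. All exact periods up to `m` are
#' reported (including lengths that do not divide `m`).
#'
#' @param system a [pds].
#' @param m maximum cycle length to search (kept small in practice;
#'   biological limit cycles are typically short).
#' @param solution_limit passed to [solve_system()].
#' @return An object of class `cycle_set`: list with `steady_states`
#'   (matrix), `cycles` (list of `list(states, period)`),
#'   `searched_length`, `p`, `nvars`.
#' @export
limit_cycles <- function(system, m, solution_limit = 2^20) {
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("cycle length bound m must be >= 1")
  n <- system$nvars
  p <- system$p
  seen <- new.env(parent = emptyenv())
  steady <- list()
  cycles <- list()
  for (d in seq_len(m)) {
    sols <- solve_system(unrolled_equations(system, d), p = p, nvars = n * d,
                         solution_limit = solution_limit)
    if (nrow(sols) == 0L) next
    starts <- sols[, seq_len(n), drop = FALSE]
    for (r in seq_len(nrow(starts))) {
      key <- state_to_string(starts[r, ])
      if (!is.null(seen[[key]])) next
      orbit <- orbit_of(system, starts[r, ])
      for (rr in seq_len(nrow(orbit))) seen[[state_to_string(orbit[rr, ])]] <- TRUE
      if (nrow(orbit) == 1L) {
        steady[[length(steady) + 1L]] <- orbit
      } else {
        cycles[[length(cycles) + 1L]] <- list(states = orbit, period = nrow(orbit))
      }
    }
  }
  ss <- if (length(steady)) do.call(rbind, steady) else matrix(0L, 0L, n)
  if (nrow(ss) > 1L) {
    ss <- ss[order(vapply(asplit(ss, 1), state_to_string, character(1))), , drop = FALSE]
  }
  if (length(cycles) > 1L) {
    ord <- order(vapply(cycles, function(cy) cy$period, integer(1)),
                 vapply(cycles, function(cy) state_to_string(cy$states[1L, ]), character(1)))
    cycles <- cycles[ord]
  }
  structure(list(steady_states = ss, cycles = cycles, searched_length = m,
                 p = p, nvars = n),
            class = "cycle_set")
}

# orbit of a periodic state, rotated to start at the lexicographically
# smallest member
orbit_of <- function(system, state) {
  path <- list(state)
  cur <- pds_evaluate(system, state)
  start_key <- state_to_string(state)
  while (state_to_string(cur) != start_key) {
    path[[length(path) + 1L]] <- cur
    cur <- pds_evaluate(system, cur)
    if (length(path) > system$p^system$nvars) stop("state is not periodic")
  }
  orbit <- do.call(rbind, path)
  keys <- vapply(asplit(orbit, 1), state_to_string, character(1))
  k <- which.min(keys)
  if (k > 1L) orbit <- orbit[c(k:nrow(orbit), 1:(k - 1L)), , drop = FALSE]
  orbit
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("<cycle_set: searched length <= %d over F_%d^%d>\n",
              x$searched_length, x$p, x$nvars))
  cat(sprintf("  steady states (%d):\n", nrow(x$steady_states)))
  for (r in seq_len(min(nrow(x$steady_states), 20L))) {
    cat("    ", state_to_string(x$steady_states[r, ]), "\n", sep = "")
  }
  if (nrow(x$steady_states) > 20L) cat("    ...\n")
  cat(sprintf("  limit cycles (%d):\n", length(x$cycles)))
  for (cy in x$cycles) {
    cat(sprintf("    period %d: %s\n", cy$period,
                paste(vapply(asplit(cy$states, 1), state_to_string, character(1)),
                      collapse = " -> ")))
  }
  invisible(x)
}
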