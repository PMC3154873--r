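#' Exhaustive phase space (state transition graph)
#'
#' For models small enough to enumerate, builds the directed graph on all
#' `p^n` states with the single out-edge `x -> f(x)` per state, extracts
#' the attractors (the cycles of this functional graph), and labels every
#' state with its basin (weakly connected component — one per attractor).
#' Larger models are refused with a pointer to the algebraic route
#' ([steady_states()] / [limit_cycles()]), which does not need the graph.
#'
#' @param system a [pds].
#' @param exhaustive_threshold refuse when `p^nvars` exceeds this
#'   (default `2^20` states).
#' @return An object of class `phase_space`: list with `states` (matrix),
#'   `succ` (successor row index per state), `attractors` (list of
#'   `list(states, period)`), `component` (attractor/basin id per state),
#'   `component_sizes`, `p`, `nvars`.
#' @export
build_phase_space <- function(system, exhaustive_threshold = 2^20) {
  p <- system$p
  n <- system$nvars
  N <- as.numeric(p)^n
  if (N > exhaustive_threshold) {
    stop_refusal(paste0("state space has p^n = ", N,
                        " states, above the exhaustive threshold (",
                        exhaustive_threshold,
                        "); use steady_states()/limit_cycles() instead"))
  }
  states <- all_states(p, n)
  succmat <- pds_evaluate_states(system, states)
  succ <- as.integer(state_index(succmat, p))

  N <- nrow(states)
  comp <- integer(N)            # 0 = unassigned; else attractor id
  on_path <- integer(N)         # visit stamp for the current walk
  attractors <- list()
  for (s in seq_len(N)) {
    if (comp[s] != 0L) next
    path <- integer(0)
    v <- s
    while (comp[v] == 0L && on_path[v] == 0L) {
      on_path[v] <- length(path) + 1L
      path <- c(path, v)
      v <- succ[v]
    }
    if (comp[v] == 0L) {
      # found a new cycle: path[on_path[v] .. end]
      cyc <- path[on_path[v]:length(path)]
      id <- length(attractors) + 1L
      attractors[[id]] <- cyc
      comp[cyc] <- id
    }
    comp[path] <- comp[v]
    on_path[path] <- 0L
  }
  attractors <- lapply(attractors, function(cyc) {
    orbit <- states[cyc, , drop = FALSE]
    keys <- vapply(asplit(orbit, 1), state_to_string, character(1))
    k <- which.min(keys)
    if (k > 1L) orbit <- orbit[c(k:nrow(orbit), 1:(k - 1L)), , drop = FALSE]
    list(states = orbit, period = nrow(orbit))
  })
  structure(list(states = states, succ = succ, attractors = attractors,
                 component = comp, component_sizes = tabulate(comp),
                 p = p, nvars = n),
            class = "phase_space")
}

#' @export
print.phase_space <- function(x, ...) {
  cat(sprintf("<phase_space: %d states over F_%d^%d, %d attractor(s)>\n",
              nrow(x$states), x$p, x$nvars, length(x$attractors)))
  for (a in x$attractors) {
    if (a$period == 1L) {
      cat("  steady state ", state_to_string(a$states[1L, ]), "\n", sep = "")
    } else {
      cat(sprintf("  cycle of period %d starting %s\n", a$period,
                  state_to_string(a$states[1L, ])))
    }
  }
  invisible(x)
}

#' Convert phase-space attractors to a cycle set
#'
#' Cross-method bridge: the attractors read off the exhaustive graph in
#' the same structure that [limit_cycles()] returns, so the two routes
#' can be compared directly.
#'
#' @param ps a [build_phase_space()] result.
#' @param m report cycles of period up to `m` only (`Inf` for all).
#' @return A `cycle_set`.
#' @export
phase_space_cycle_set <- function(ps, m = Inf) {
  steady <- list()
  cycles <- list()
  for (a in ps$attractors) {
    if (a$period == 1L) {
      steady[[length(steady) + 1L]] <- a$states
    } else if (a$period <= m) {
      cycles[[length(cycles) + 1L]] <- a
    }
  }
  ss <- if (length(steady)) do.call(rbind, steady) else matrix(0L, 0L, ps$nvars)
  if (nrow(ss) > 1L) {
    ss <- ss[order(vapply(asplit(ss, 1), state_to_string, character(1))), , drop = FALSE]
  }
  if (length(cycles) > 1L) {
    ord <- order(vapply(cycles, function(cy) cy$period, integer(1)),
                 vapply(cycles, function(cy) state_to_string(cy$states[1L, ]), character(1)))
    cycles <- cycles[ord]
  }
  structure(list(steady_states = ss, cycles = cycles,
                 searched_length = if (is.finite(m)) as.integer(m) else
                   max(c(1L, vapply(cycles, function(cy) cy$period, integer(1)))),
                 p = ps$p, nvars = ps$nvars),
            class = "cycle_set")
}

#' Trajectory from an initial state
#'
#' Repeatedly applies the update map until a state repeats; the finite
#' state space guarantees termination. Returns the transient prefix and
#' the attractor (steady state or limit cycle) that is eventually
#' entered.
#'
#' @param system a [pds].
#' @param start initial state (integer vector or digit string).
#' @return Object of class `pds_trajectory`: list with `path` (all
#'   states visited once, transient then attractor), `transient`
#'   (matrix, possibly 0 rows), `attractor` (`list(states, period)`),
#'   `type` (`"steady_state"` or `"limit_cycle"`).
#' @export
trajectory <- function(system, start) {
  if (is.character(start)) start <- string_to_state(start)
  start <- as.integer(start)
  if (length(start) != system$nvars) {
    stop("initial state has length ", length(start), ", expected ", system$nvars)
  }
  seen <- new.env(parent = emptyenv())
  path <- list()
  cur <- start
  repeat {
    key <- state_to_string(cur)
    if (!is.null(seen[[key]])) {
      j <- seen[[key]]
      break
    }
    seen[[key]] <- length(path) + 1L
    path[[length(path) + 1L]] <- cur
    cur <- pds_evaluate(system, cur)
  }
  all_mat <- do.call(rbind, path)
  attractor <- all_mat[j:nrow(all_mat), , drop = FALSE]
  transient <- if (j > 1L) all_mat[1:(j - 1L), , drop = FALSE] else
    matrix(0L, 0L, system$nvars)
  structure(list(path = all_mat,
                 transient = transient,
                 attractor = list(states = attractor, period = nrow(attractor)),
                 type = if (nrow(attractor) == 1L) "steady_state" else "limit_cycle"),
            class = "pds_trajectory")
}

#' @export
print.pds_trajectory <- function(x, ...) {
  keys <- vapply(asplit(x$path, 1), state_to_string, character(1))
  cat(paste(keys, collapse = " -> "))
  if (x$type == "steady_state") {
    cat("  [reaches steady state]\n")
  } else {
    cat(sprintf("  [enters %d-cycle]\n", x$attractor$period))
  }
  invisible(x)
}
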