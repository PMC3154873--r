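#' Run a full analysis of a model
#'
#' One-call driver mirroring the analysis choices a modeler makes:
#' exhaustive *simulation* of the phase space for small models, or the
#' *algorithm* route — steady states and limit cycles by polynomial
#' system solving — for models of any size. The wiring diagram is always
#' computed (it never requires enumerating states). Optional extras: a
#' sequential update schedule (analyzed by collapsing one sweep to a
#' synchronous system), a trajectory from an initial state, the
#' conjunctive/disjunctive fast path when it applies, and flagging of
#' embedding-artifact states for models converted from multi-valued
#' logical tables.
#'
#' @param model a [pds] or [ppds].
#' @param mode `"algorithm"` (algebraic; any size) or `"simulation"`
#'   (exhaustive; refused above `exhaustive_threshold` states).
#' @param cycle_length maximum limit-cycle length `m` to search
#'   (algorithm mode); `1` finds steady states only. Kept small by
#'   default — composition effort grows quickly with `m` and biological
#'   limit cycles are typically short.
#' @param schedule optional permutation of `1..n` for sequential
#'   updates; steady states are schedule-invariant, so this only affects
#'   cycles and trajectories.
#' @param initial_state optional state (vector or digit string): also
#'   compute its trajectory.
#' @param out_dir optional directory: write `report.json`, `report.txt`
#'   and DOT files there.
#' @param exhaustive_threshold maximum `p^n` for simulation mode.
#' @return Object of class `pds_report` (a list): `wiring`, `attractors`
#'   (a `cycle_set`), optionally `phase_space`, `trajectory`,
#'   `conjunctive` (with a `"fast-path"` provenance tag), `artifacts`,
#'   and for probabilistic models `true_steady_states` /
#'   `transition_graph`.
#' @export
run_analysis <- function(model, mode = c("algorithm", "simulation"),
                         cycle_length = 1L, schedule = NULL,
                         initial_state = NULL, out_dir = NULL,
                         exhaustive_threshold = 2^20) {
  mode <- match.arg(mode)
  cycle_length <- as.integer(cycle_length)
  if (cycle_length < 1L) stop_precondition("cycle_length must be >= 1")
  report <- list(schema_version = "1.0",
                 p = model$p, nvars = model$nvars, mode = mode,
                 cycle_length = cycle_length)

  if (inherits(model, "ppds")) {
    report$wiring <- ppds_wiring_diagram(model)
    if (mode == "simulation") {
      report$transition_graph <- probabilistic_transition_graph(
        model, exhaustive_threshold = exhaustive_threshold)
    }
    report$true_steady_states <- true_steady_states(model)
    class(report) <- "pds_report"
    if (!is.null(out_dir)) write_report(report, out_dir)
    return(report)
  }

  system <- model
  if (!is.null(schedule)) {
    system <- sequential_compose(model, schedule)
    report$schedule <- as.integer(schedule)
  }
  report$wiring <- functional_wiring_diagram(model, signs = model$p == 2L)

  if (mode == "simulation") {
    ps <- build_phase_space(system, exhaustive_threshold = exhaustive_threshold)
    report$phase_space <- ps
    report$attractors <- phase_space_cycle_set(ps)
  } else {
    report$attractors <- limit_cycles(system, cycle_length)
  }

  if (model$p == 2L) {
    cls <- detect_class(system)
    if (cls != "neither") {
      summ <- suppressMessages(conjunctive_attractors(system))
      if (!summ$fallback) {
        summ$provenance <- "fast-path"
        report$conjunctive <- summ
      }
    }
  }

  if (!is.null(initial_state)) {
    report$trajectory <- trajectory(system, initial_state)
  }

  ml <- attr(model, "max_levels")
  if (!is.null(ml)) {
    states <- rbind(report$attractors$steady_states,
                    do.call(rbind, lapply(report$attractors$cycles,
                                          function(cy) cy$states)))
    if (!is.null(states) && nrow(states)) {
      flags <- flag_artifact_states(states, ml)
      report$artifacts <- apply(states[flags, , drop = FALSE], 1L, state_to_string)
    }
  }
  class(report) <- "pds_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# wiring diagram of a probabilistic system: union of the supports of all
# candidate rules per coordinate; signs are not defined (rules may
# disagree), so edges are unsigned
ppds_wiring_diagram <- function(pp) {
  n <- pp$nvars
  from <- integer(0)
  to <- integer(0)
  for (j in seq_len(n)) {
    supp <- sort(unique(unlist(lapply(pp$functions[[j]], fp_support))))
    from <- c(from, supp)
    to <- c(to, rep.int(j, length(supp)))
  }
  edges <- data.frame(from = from, to = to, sign = NA_character_,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nvars = n, edges = edges), class = "wiring_diagram")
}

cycle_set_to_list <- function(cs) {
  list(steady_states = apply(cs$steady_states, 1L, state_to_string),
       cycles = lapply(cs$cycles, function(cy) {
         list(period = cy$period,
              states = apply(cy$states, 1L, state_to_string))
       }),
       searched_length = cs$searched_length)
}

#' Serialize a report to JSON
#'
#' Stable, versioned schema; states are digit strings with `x1` leftmost.
#'
#' @param report a `pds_report`.
#' @return JSON string.
#' @export
report_to_json <- function(report) {
  out <- list(schema_version = report$schema_version,
              field = report$p, nvars = report$nvars, mode = report$mode)
  if (!is.null(report$schedule)) out$schedule <- report$schedule
  if (!is.null(report$wiring)) {
    out$wiring <- report$wiring$edges
  }
  if (!is.null(report$attractors)) {
    out$attractors <- cycle_set_to_list(report$attractors)
  }
  if (!is.null(report$true_steady_states)) {
    out$true_steady_states <- apply(report$true_steady_states, 1L, state_to_string)
  }
  if (!is.null(report$conjunctive)) {
    cj <- report$conjunctive
    out$conjunctive <- list(class = cj$class, provenance = cj$provenance,
                            loop_number = cj$loop_number,
                            admissible_periods = cj$admissible_periods,
                            steady_states = apply(cj$steady_states, 1L,
                                                  state_to_string))
  }
  if (!is.null(report$trajectory)) {
    tr <- report$trajectory
    out$trajectory <- list(path = apply(tr$path, 1L, state_to_string),
                           type = tr$type,
                           attractor_period = tr$attractor$period)
  }
  if (!is.null(report$artifacts)) out$artifacts <- report$artifacts
  jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(report_to_json(report), file.path(out_dir, "report.json"))
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(out_dir, "report.txt"))
  if (!is.null(report$wiring)) {
    to_dot(report$wiring, file.path(out_dir, "wiring.dot"))
  }
  if (!is.null(report$phase_space)) {
    to_dot(report$phase_space, file.path(out_dir, "phase_space.dot"))
  }
  if (!is.null(report$transition_graph)) {
    to_dot(report$transition_graph, file.path(out_dir, "prob_phase_space.dot"))
  }
  if (!is.null(report$trajectory)) {
    to_dot(report$trajectory, file.path(out_dir, "trajectory.dot"))
  }
  invisible(report)
}

#' @export
print.pds_report <- function(x, ...) {
  cat(sprintf("== analysis report (F_%d, %d variables, %s mode) ==\n",
              x$p, x$nvars, x$mode))
  if (!is.null(x$wiring)) {
    cat(sprintf("wiring diagram: %d functional edges\n", nrow(x$wiring$edges)))
  }
  if (!is.null(x$attractors)) print(x$attractors)
  if (!is.null(x$true_steady_states)) {
    cat(sprintf("true steady states (%d):\n", nrow(x$true_steady_states)))
    for (r in seq_len(nrow(x$true_steady_states))) {
      cat("  ", state_to_string(x$true_steady_states[r, ]), "\n", sep = "")
    }
  }
  if (!is.null(x$conjunctive)) print(x$conjunctive)
  if (!is.null(x$trajectory)) print(x$trajectory)
  if (!is.null(x$artifacts) && length(x$artifacts)) {
    cat("embedding-artifact attractor states (out-of-range levels):\n")
    cat("  ", paste(x$artifacts, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
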