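#' Classify a Boolean system as conjunctive, disjunctive, or neither
#'
#' A conjunctive network updates every variable by a pure AND of its
#' inputs (canonical polynomial: a single squarefree monomial with
#' coefficient 1, or a constant); a disjunctive network by a pure OR
#' (canonical polynomial equal to the OR-polynomial
#' `1 + prod(1 + x_j)` of its inputs, or a constant).
#'
#' @param system a [pds] over F_2.
#' @return `"conjunctive"`, `"disjunctive"`, or `"neither"`. A system
#'   whose every rule is constant or a single variable is both AND and
#'   OR; it is reported as `"conjunctive"`.
#' @export
detect_class <- function(system) {
  if (system$p != 2L) stop("conjunctive/disjunctive analysis requires p = 2")
  is_and <- function(f) {
    fp_is_constant(f) ||
      (length(f$coef) == 1L && f$coef[[1L]] == 1L && all(f$expo %in% c(0L, 1L)))
  }
  is_or <- function(f) {
    if (fp_is_constant(f)) return(TRUE)
    supp <- fp_support(f)
    fp_equal(f, or_polynomial(supp, f$nvars))
  }
  if (all(vapply(system$functions, is_and, logical(1)))) return("conjunctive")
  if (all(vapply(system$functions, is_or, logical(1)))) return("disjunctive")
  "neither"
}

# OR of the variables in vars, as a canonical F_2 polynomial
or_polynomial <- function(vars, nvars) {
  acc <- fp_zero(2L, nvars)
  for (v in vars) {
    xv <- fp_var(v, 2L, nvars)
    acc <- fp_add(fp_add(acc, xv), fp_mul(acc, xv))
  }
  acc
}

gcd2 <- function(a, b) {
  while (b != 0L) {
    t <- a %% b
    a <- b
    b <- t
  }
  a
}

#' Loop number of a strongly connected wiring diagram
#'
#' The greatest common divisor of the lengths of all directed cycles.
#' For a strongly connected digraph it equals the gcd of
#' `dist(u) + 1 - dist(v)` over all edges `u -> v`, with `dist` the
#' BFS distance from any fixed node — no cycle enumeration needed. In a
#' conjunctive or disjunctive network, every limit-cycle period divides
#' the loop number, so it bounds the admissible dynamics essentially for
#' free.
#'
#' @param wd a [functional_wiring_diagram()] result.
#' @return Positive integer.
#' @export
loop_number <- function(wd) {
  n <- wd$nvars
  if (nrow(wd$edges) == 0L) stop("wiring diagram has no edges, hence no cycles")
  g <- igraph::graph_from_edgelist(as.matrix(wd$edges[, c("from", "to")]),
                                   directed = TRUE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  if (!igraph::is_connected(g, mode = "strong")) {
    stop("wiring diagram is not strongly connected")
  }
  d <- as.numeric(igraph::distances(g, v = 1L, mode = "out"))
  ln <- 0L
  for (k in seq_len(nrow(wd$edges))) {
    u <- wd$edges$from[k]
    v <- wd$edges$to[k]
    ln <- gcd2(ln, abs(as.integer(d[u] + 1 - d[v])))
  }
  if (ln == 0L) stop("degenerate wiring diagram: no directed cycle found")
  ln
}

divisors_of <- function(m) which(m %% seq_len(m) == 0L)

#' Fast-path dynamic summary for conjunctive/disjunctive networks
#'
#' For strongly connected conjunctive (all-AND) or disjunctive (all-OR)
#' Boolean networks, key dynamic features follow from the wiring alone:
#' the only steady states are the all-zeros and all-ones states, and
#' every limit-cycle period divides the loop number of the wiring
#' diagram. Disjunctive networks are covered by the 0/1 complementation
#' duality (complementing every state turns ORs into ANDs and preserves
#' the wiring), so no separate analysis is needed. When the system is
#' neither conjunctive nor disjunctive, or the wiring is not strongly
#' connected, the function falls back to the general algebraic solver
#' with a notice.
#'
#' @param system a [pds] over F_2.
#' @return Object of class `conjunctive_summary`: list with `class`,
#'   `strongly_connected`, `fallback`, `loop_number`,
#'   `admissible_periods` (divisors of the loop number), and
#'   `steady_states` (each verified by evaluation).
#' @export
conjunctive_attractors <- function(system) {
  cls <- detect_class(system)
  wd <- functional_wiring_diagram(system, signs = FALSE)
  strongly <- FALSE
  if (nrow(wd$edges) > 0L) {
    g <- igraph::graph_from_edgelist(as.matrix(wd$edges[, c("from", "to")]),
                                     directed = TRUE)
    g <- igraph::add_vertices(g, max(0L, system$nvars - igraph::vcount(g)))
    strongly <- igraph::is_connected(g, mode = "strong")
  }
  if (cls == "neither" || !strongly) {
    message("not a strongly connected conjunctive/disjunctive network; ",
            "falling back to the general solver")
    return(structure(list(class = cls, strongly_connected = strongly,
                          fallback = TRUE, loop_number = NA_integer_,
                          admissible_periods = NULL,
                          steady_states = steady_states(system)),
                     class = "conjunctive_summary"))
  }
  ln <- loop_number(wd)
  n <- system$nvars
  cand <- rbind(rep(0L, n), rep(1L, n))
  ok <- vapply(seq_len(nrow(cand)), function(r) {
    all(pds_evaluate(system, cand[r, ]) == cand[r, ])
  }, logical(1))
  structure(list(class = cls, strongly_connected = TRUE, fallback = FALSE,
                 loop_number = ln,
                 admissible_periods = divisors_of(ln),
                 steady_states = cand[ok, , drop = FALSE]),
            class = "conjunctive_summary")
}

#' @export
print.conjunctive_summary <- function(x, ...) {
  cat(sprintf("<conjunctive_summary: %s%s>\n", x$class,
              if (x$fallback) ", general-solver fallback" else ", fast path"))
  if (!x$fallback) {
    cat("  loop number:", x$loop_number, "\n")
    cat("  admissible cycle periods:", paste(x$admissible_periods, collapse = ", "), "\n")
  }
  cat("  steady states:",
      paste(vapply(asplit(x$steady_states, 1), state_to_string, character(1)),
            collapse = ", "), "\n")
  invisible(x)
}
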