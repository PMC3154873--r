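#' Convert a set of Boolean rules to a polynomial dynamical system
#'
#' Rule `i` is a Boolean expression (see [parse_boolean()]) giving the
#' update of `x_i`; the system has one rule per variable, so `nvars`
#' equals the number of rules.
#'
#' @param rules character vector of Boolean expressions, one per
#'   variable.
#' @return A [pds] over F_2 whose truth tables equal those of the rules.
#' @examples
#' boolean_rules_to_pds(c("x2", "x1 AND NOT x2"))
#' @export
boolean_rules_to_pds <- function(rules) {
  n <- length(rules)
  if (n < 1L) stop("need at least one rule")
  pds(lapply(rules, parse_boolean, nvars = n), p = 2L)
}

# enumerate tuples with per-position bounds (levels 0..bounds[j]),
# first position most significant -- mixed-radix analogue of all_states()
mixed_radix_states <- function(bounds) {
  sizes <- bounds + 1L
  N <- prod(sizes)
  out <- matrix(0L, N, length(bounds))
  idx <- 0:(N - 1)
  for (j in length(bounds):1) {
    out[, j] <- as.integer(idx %% sizes[j])
    idx <- idx %/% sizes[j]
  }
  out
}

#' Multi-valued logical transition tables
#'
#' A logical model in which variable `i` takes levels `0..max_levels[i]`
#' (so different variables may have different numbers of levels) and each
#' variable carries a full transition table over all input combinations.
#'
#' @param max_levels integer vector: the maximum level of each variable
#'   (a Boolean variable has `max_level = 1`).
#' @param outputs list with one integer vector per variable: the next
#'   level of that variable for every input tuple, in mixed-radix row
#'   order (variable 1 most significant, variable `j` ranging
#'   `0..max_levels[j]`).
#' @return An object of class `logical_table`.
#' @export
logical_table <- function(max_levels, outputs) {
  max_levels <- as.integer(max_levels)
  n <- length(max_levels)
  stopifnot(n >= 1L, all(max_levels >= 1L), length(outputs) == n)
  N <- prod(max_levels + 1L)
  for (i in seq_len(n)) {
    v <- as.integer(outputs[[i]])
    if (length(v) != N) {
      stop("table for variable ", i, " has ", length(v),
           " entries; expected ", N, " (all input combinations)")
    }
    if (any(v < 0L | v > max_levels[i])) {
      stop("outputs of variable ", i, " exceed its maximum level ", max_levels[i])
    }
    outputs[[i]] <- v
  }
  structure(list(max_levels = max_levels, outputs = outputs, nvars = n),
            class = "logical_table")
}

#' @export
print.logical_table <- function(x, ...) {
  cat(sprintf("<logical_table, %d variables, max levels %s>\n",
              x$nvars, paste(x$max_levels, collapse = ",")))
  invisible(x)
}

#' Embed a multi-valued logical model over a common prime field
#'
#' Algebraic models need all variables over one field F_p, so a model
#' whose variables have different numbers of levels is *extended*: each
#' variable's table gains rows/columns for the out-of-range input levels
#' `max_level+1 .. p-1` by repeating its last defined row (equivalently,
#' input levels are clamped to the variable's declared maximum before
#' lookup), applied per input variable independently; outputs are clamped
#' to the target variable's own maximum. The extended states are
#' artifacts of the embedding: they are reachable in the resulting PDS
#' and attractor reports flag any attractor that contains a level above a
#' variable's declared maximum (see [flag_artifact_states()]) rather than
#' silently dropping it.
#'
#' @param tables a [logical_table].
#' @param p target prime; must exceed every variable's maximum level.
#' @return A [pds] over F_p with attribute `"max_levels"` recording the
#'   declared level ranges.
#' @export
extend_multivalued <- function(tables, p) {
  stopifnot(inherits(tables, "logical_table"))
  p <- as_field_p(p)
  n <- tables$nvars
  if (p < max(tables$max_levels) + 1L) {
    stop("p = ", p, " is smaller than some variable's level count; need p >= ",
         max(tables$max_levels) + 1L)
  }
  grid <- all_states(p, n)
  clamped <- grid
  for (j in seq_len(n)) clamped[, j] <- pmin(grid[, j], tables$max_levels[j])
  # row index of the clamped tuple in the original mixed-radix table
  sizes <- tables$max_levels + 1L
  idx <- numeric(nrow(grid))
  for (j in seq_len(n)) idx <- idx * sizes[j] + clamped[, j]
  idx <- idx + 1
  fns <- lapply(seq_len(n), function(i) {
    vals <- pmin(tables$outputs[[i]][idx], tables$max_levels[i])
    interpolate_table(vals, p, n)
  })
  out <- pds(fns, p = p)
  attr(out, "max_levels") <- tables$max_levels
  out
}

#' Flag embedding-artifact states
#'
#' States containing a level above a variable's declared maximum only
#' exist because of the common-field embedding and should be ignored
#' when interpreting the dynamics.
#'
#' @param states integer matrix, one state per row (or a single state
#'   vector).
#' @param max_levels declared per-variable maxima.
#' @return Logical vector: `TRUE` where the state is an out-of-range
#'   artifact.
#' @export
flag_artifact_states <- function(states, max_levels) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1L)
  apply(states, 1L, function(s) any(s > max_levels))
}

#' Sequential update schedule collapsed to one synchronous system
#'
#' Under a sequential schedule every variable is updated once per time
#' step, in the given order, each update seeing the already-updated
#' values of its predecessors. One full sweep is itself a deterministic
#' map F_p^n -> F_p^n; this function computes it symbolically: walking
#' the schedule, the update polynomial of each variable is substituted
#' into the rules of the variables updated after it. Fixed points are
#' unchanged by the schedule (updating any coordinate at a steady state
#' changes nothing), which the test-suite checks.
#'
#' @param system a [pds] (the synchronous rules).
#' @param schedule integer permutation of `1..nvars`: update order.
#' @return A [pds] `F` with `F(x)` = state after one sequential sweep.
#' @export
sequential_compose <- function(system, schedule) {
  n <- system$nvars
  schedule <- as.integer(schedule)
  if (length(schedule) != n || !setequal(schedule, seq_len(n))) {
    stop("schedule must be a permutation of 1..", n)
  }
  cur <- lapply(seq_len(n), fp_var, p = system$p, nvars = n)  # x as-is
  for (i in schedule) {
    cur[[i]] <- fp_subst_polys(system$functions[[i]], cur)
  }
  pds(cur, p = system$p)
}

#' Check the one-step continuity of a system
#'
#' A logical model is *continuous* when no variable changes by more than
#' one level per update (no jumps from high to low). This property is a
#' modeling convention of some logical-model tools, not something the
#' polynomial conversion enforces; this validator reports it by
#' exhaustive check of the state space.
#'
#' @param system a [pds].
#' @param exhaustive_threshold refuse when `p^nvars` exceeds this.
#' @return `TRUE` if `|f_i(x) - x_i| <= 1` for all states and
#'   coordinates.
#' @export
pds_is_continuous <- function(system, exhaustive_threshold = 2^20) {
  N <- system$p^system$nvars
  if (N > exhaustive_threshold) {
    stop("state space too large for exhaustive continuity check (p^n = ", N, ")")
  }
  states <- all_states(system$p, system$nvars)
  succ <- pds_evaluate_states(system, states)
  all(abs(succ - states) <= 1L)
}
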