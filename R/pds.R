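#' Polynomial dynamical systems
#'
#' A polynomial dynamical system (PDS) over the prime field F_p is a map
#' `f = (f1, ..., fn) : F_p^n -> F_p^n` whose coordinate functions are
#' polynomials; iterating `f` gives a deterministic discrete-time
#' dynamical system. Each variable `x_i` models a biological quantity (a
#' gene, protein, or abstract level) and `f_i` is its synchronous update
#' rule. Every function on a finite field is polynomial, so Boolean
#' networks and multi-valued logical models embed without loss.
#'
#' @param functions list of `n` [fpoly] objects, all over the same field
#'   and in `n` variables; `functions[[i]]` updates `x_i`.
#' @param p prime field order (defaults to the field of the first
#'   polynomial).
#' @return An object of class `pds` with elements `functions`, `p`,
#'   `nvars`.
#' @examples
#' f <- pds(list(fp_var(2, 2, 2), fp_mul(fp_var(1, 2, 2), fp_var(2, 2, 2))))
#' pds_evaluate(f, c(1, 0))
#' @export
pds <- function(functions, p = NULL) {
  stopifnot(is.list(functions), length(functions) >= 1L)
  if (is.null(p)) p <- functions[[1L]]$p
  p <- as_field_p(p)
  n <- length(functions)
  for (i in seq_len(n)) {
    f <- functions[[i]]
    if (!inherits(f, "fpoly")) stop("functions[[", i, "]] is not an fpoly")
    if (f$p != p) stop("functions[[", i, "]] is over F_", f$p, ", expected F_", p)
    if (f$nvars != n) {
      stop("functions[[", i, "]] has ", f$nvars, " variables, expected ", n)
    }
  }
  structure(list(functions = lapply(functions, canonicalize),
                 p = p, nvars = n),
            class = "pds")
}

#' @export
print.pds <- function(x, ...) {
  cat(sprintf("<pds over F_%d, %d variables>\n", x$p, x$nvars))
  show <- min(x$nvars, 12L)
  for (i in seq_len(show)) {
    cat(sprintf("  f%d = %s\n", i, format(x$functions[[i]])))
  }
  if (x$nvars > show) cat(sprintf("  ... (%d more)\n", x$nvars - show))
  invisible(x)
}

#' Apply a PDS to a state
#'
#' One synchronous update: returns `(f1(x), ..., fn(x))` with all
#' arithmetic modulo `p`.
#'
#' @param system a [pds].
#' @param state integer vector of length `nvars` with entries in
#'   `0..p-1`.
#' @return Integer vector: the successor state.
#' @export
pds_evaluate <- function(system, state) {
  state <- as.integer(state)
  if (length(state) != system$nvars) {
    stop("state has length ", length(state), ", expected ", system$nvars)
  }
  if (any(state < 0L | state >= system$p)) {
    stop("state entries must lie in 0..", system$p - 1L)
  }
  vapply(system$functions, fp_eval, integer(1), state = state)
}

#' Apply a PDS to many states at once
#'
#' @param system a [pds].
#' @param states integer matrix, one state per row.
#' @return Integer matrix of successor states (same shape).
#' @export
pds_evaluate_states <- function(system, states) {
  out <- matrix(0L, nrow(states), system$nvars)
  for (i in seq_len(system$nvars)) {
    out[, i] <- fp_eval_states(system$functions[[i]], states)
  }
  out
}

#' Symbolic self-composition of a PDS
#'
#' Returns the PDS computing `f^m = f o f o ... o f` (`m` times), each
#' coordinate canonicalized after every substitution step so per-variable
#' degrees stay below `p`. States of a limit cycle whose length divides
#' `m` are exactly the fixed points of the composed system.
#'
#' @param system a [pds].
#' @param m positive integer.
#' @return A [pds] computing the `m`-step update.
#' @export
pds_compose <- function(system, m) {
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("composition power m must be a positive integer")
  out <- system$functions
  steps <- m - 1L
  while (steps > 0L) {
    out <- lapply(out, fp_subst_polys, glist = system$functions)
    steps <- steps - 1L
  }
  pds(out, p = system$p)
}

#' Identity system
#'
#' @param p prime field order.
#' @param nvars number of variables.
#' @return The [pds] with `f_i = x_i`.
#' @export
pds_identity <- function(p, nvars) {
  pds(lapply(seq_len(nvars), fp_var, p = p, nvars = nvars), p = p)
}

#' Exact equality of two systems as functions
#'
#' @param a,b [pds] objects.
#' @return `TRUE` if every coordinate agrees (canonical forms identical).
#' @export
pds_equal <- function(a, b) {
  if (a$p != b$p || a$nvars != b$nvars) return(FALSE)
  all(vapply(seq_len(a$nvars),
             function(i) fp_equal(a$functions[[i]], b$functions[[i]]),
             logical(1)))
}

# ---- state helpers ------------------------------------------------------

#' Convert between states and digit strings
#'
#' States are printed as digit strings reading left to right as
#' `x1 x2 ... xn` (most significant variable first), e.g. `"010"` for
#' `x1=0, x2=1, x3=0`. This matches the usual binary-string convention
#' for Boolean network states; reversed conventions are a classic
#' interoperability bug, so the orientation is fixed package-wide.
#'
#' @param state integer vector.
#' @return `state_to_string`: a character scalar.
#' @export
state_to_string <- function(state) paste(as.integer(state), collapse = "")

#' @rdname state_to_string
#' @param s digit string, one character per variable (levels 0-9).
#' @return `string_to_state`: an integer vector.
#' @export
string_to_state <- function(s) {
  s <- gsub("[ ,()]", "", s)
  if (!grepl("^[0-9]+$", s)) stop("state string must consist of digits: ", s)
  as.integer(strsplit(s, "")[[1L]])
}

#' Enumerate all states of F_p^n
#'
#' Rows are ordered so that the digit strings appear in increasing
#' lexicographic order (x1 most significant).
#'
#' @param p field order.
#' @param nvars number of variables.
#' @return Integer matrix with `p^nvars` rows.
#' @export
all_states <- function(p, nvars) {
  p <- as.integer(p)
  nvars <- as.integer(nvars)
  if (nvars == 0L) return(matrix(0L, 1L, 0L))
  N <- p^nvars
  if (N > 2^26) stop("state space too large to enumerate: p^n = ", N)
  idx <- 0:(N - 1)
  out <- matrix(0L, N, nvars)
  for (j in nvars:1) {
    out[, j] <- as.integer(idx %% p)
    idx <- idx %/% p
  }
  out
}

# row index (1-based) of a state in the all_states() ordering
state_index <- function(states, p) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1L)
  n <- ncol(states)
  idx <- numeric(nrow(states))
  for (j in seq_len(n)) idx <- idx * p + states[, j]
  idx + 1
}
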