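# Finite-field interpolation: every function F_p^k -> F_p is represented
# by a unique polynomial with per-variable degree <= p-1. Coefficients
# are recovered axis by axis with the inverse of the p x p Vandermonde
# matrix V[v+1, e+1] = v^e (mod p), which is exactly multivariate
# Lagrange interpolation written as a linear transform.

mod_inverse <- function(a, p) {
  a <- a %% p
  for (b in seq_len(p - 1L)) if ((a * b) %% p == 1L) return(as.integer(b))
  stop("no inverse of ", a, " mod ", p)
}

mat_inv_modp <- function(M, p) {
  n <- nrow(M)
  A <- cbind(M %% p, diag(n))
  for (col in seq_len(n)) {
    piv <- which(A[col:n, col] %% p != 0L)[1L]
    if (is.na(piv)) stop("matrix not invertible mod ", p)
    piv <- piv + col - 1L
    if (piv != col) A[c(col, piv), ] <- A[c(piv, col), ]
    A[col, ] <- (A[col, ] * mod_inverse(A[col, col], p)) %% p
    for (r in seq_len(n)) {
      if (r != col && A[r, col] %% p != 0L) {
        A[r, ] <- (A[r, ] - A[r, col] * A[col, ]) %% p
      }
    }
  }
  A[, (n + 1L):(2L * n), drop = FALSE] %% p
}

vandermonde_inv <- function(p) {
  V <- outer(0:(p - 1L), 0:(p - 1L), function(v, e) {
    out <- v^e
    out[e == 0L] <- 1L
    out %% p
  })
  mat_inv_modp(V, p)
}

# values: vector of length p^k, state (a_1..a_k) at index
# 1 + sum a_j * p^(k-j) (first variable most significant, matching
# all_states()). Returns coefficient vector over exponent tuples in the
# same mixed-radix order.
interp_coeffs <- function(values, p, k, Vinv) {
  if (k == 0L) return(values %% p)
  blk <- length(values) %/% p
  child <- lapply(0:(p - 1L), function(v) {
    interp_coeffs(values[(v * blk + 1L):((v + 1L) * blk)], p, k - 1L, Vinv)
  })
  out <- numeric(length(values))
  for (e1 in 0:(p - 1L)) {
    acc <- numeric(blk)
    for (v in 0:(p - 1L)) {
      w <- Vinv[e1 + 1L, v + 1L]
      if (w != 0L) acc <- (acc + w * child[[v + 1L]]) %% p
    }
    out[(e1 * blk + 1L):((e1 + 1L) * blk)] <- acc
  }
  out
}

#' Interpolate a value table into a canonical polynomial
#'
#' Given the full table of a function on `{0..p-1}^k` (over the variables
#' in `vars`), returns the unique canonical polynomial agreeing with it
#' at every point. The inverse operation of tabulating a polynomial with
#' [fp_truth_table()]; together they realize the bijection between
#' functions on F_p^n and canonical polynomials.
#'
#' @param values integer vector of length `p^length(vars)` giving the
#'   output for every input tuple in [all_states()] row order (first
#'   listed variable most significant), or a named vector keyed by state
#'   digit strings.
#' @param p prime field order.
#' @param nvars number of variables of the ambient ring.
#' @param vars which variables the table ranges over (default: all).
#' @return An [fpoly] in the `nvars`-variable ring depending only on
#'   variables in `vars`.
#' @examples
#' # Boolean AND
#' interpolate_table(c(0, 0, 0, 1), p = 2, nvars = 2)
#' @export
interpolate_table <- function(values, p, nvars, vars = seq_len(nvars)) {
  p <- as_field_p(p)
  nvars <- as.integer(nvars)
  vars <- as.integer(vars)
  k <- length(vars)
  if (!is.null(names(values)) && all(nzchar(names(values)))) {
    keys <- vapply(asplit(all_states(p, k), 1), state_to_string, character(1))
    if (!all(keys %in% names(values))) {
      stop("incomplete table: missing entries for ",
           paste(utils::head(setdiff(keys, names(values)), 3L), collapse = ", "))
    }
    values <- values[keys]
  }
  values <- as.integer(values) %% p
  if (length(values) != p^k) {
    stop("incomplete table: expected ", p^k, " entries, got ", length(values))
  }
  co <- interp_coeffs(values, p, k, vandermonde_inv(p))
  nz <- which(co != 0)
  if (length(nz) == 0L) return(fp_zero(p, nvars))
  expo_local <- all_states(p, k)[nz, , drop = FALSE]  # exponent tuples, same radix order
  expo <- matrix(0L, length(nz), nvars)
  expo[, vars] <- expo_local
  fp_make(as.integer(co[nz]), expo, p, nvars)
}

#' Tabulate a polynomial over a variable subset
#'
#' @param f an [fpoly].
#' @param vars variables to tabulate over (default: all of the ring);
#'   variables outside `vars` must not occur in `f`.
#' @return Integer vector of length `p^length(vars)` in [all_states()]
#'   row order.
#' @export
fp_truth_table <- function(f, vars = seq_len(f$nvars)) {
  vars <- as.integer(vars)
  extra <- setdiff(fp_support(f), vars)
  if (length(extra)) {
    stop("polynomial depends on variables outside the table: x",
         paste(extra, collapse = ", x"))
  }
  grid <- all_states(f$p, length(vars))
  states <- matrix(0L, nrow(grid), f$nvars)
  states[, vars] <- grid
  fp_eval_states(f, states)
}
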