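#' Multivariate polynomials over a prime field
#'
#' The workhorse type of the package. A polynomial in `x1, ..., xn` with
#' coefficients in F_p is stored sparsely as a coefficient vector plus an
#' exponent matrix (one row per term, one column per variable). Every
#' polynomial is kept in *canonical form*: the unique representative of
#' its residue class modulo the field equations `x_i^p - x_i`. In that
#' quotient every exponent is at most `p - 1`, no zero coefficients are
#' stored, and two polynomials define the same function on F_p^n exactly
#' when their term data are identical. Canonical form is what lets
#' "variable x_i appears in f" coincide with "f genuinely depends on x_i",
#' which the wiring-diagram code relies on.
#'
#' @name fpoly
#' @keywords internal
NULL

new_fpoly <- function(p, nvars, coef, expo) {
  structure(list(p = p, nvars = nvars, coef = coef, expo = expo),
            class = "fpoly")
}

# Reduce arbitrary (coef, expo) term data to canonical form.
# Exponent reduction uses x^p = x, i.e. e -> 1 + (e-1) mod (p-1) for e > 0.
fp_canon_terms <- function(p, nvars, coef, expo) {
  coef <- as.integer(round(coef)) %% p
  if (is.null(dim(expo))) expo <- matrix(as.integer(expo), ncol = nvars)
  storage.mode(expo) <- "integer"
  if (length(coef)) {
    pos <- expo > 0L
    if (p == 2L) expo[pos] <- 1L else expo[pos] <- 1L + (expo[pos] - 1L) %% (p - 1L)
  }
  keep <- coef != 0L
  coef <- coef[keep]
  expo <- expo[keep, , drop = FALSE]
  if (length(coef) > 1L) {
    key <- do.call(paste, c(lapply(seq_len(nvars), function(j) expo[, j]), sep = ","))
    if (anyDuplicated(key)) {
      first <- !duplicated(key)
      coef <- as.integer(rowsum(coef, factor(key, levels = key[first]))) %% p
      expo <- expo[first, , drop = FALSE]
      keep <- coef != 0L
      coef <- coef[keep]
      expo <- expo[keep, , drop = FALSE]
    }
  }
  if (length(coef) > 1L) {
    # graded lexicographic, x1 > x2 > ... > xn, highest first
    deg <- rowSums(expo)
    ord <- do.call(order, c(list(-deg), lapply(seq_len(nvars), function(j) -expo[, j])))
    coef <- coef[ord]
    expo <- expo[ord, , drop = FALSE]
  }
  new_fpoly(p, nvars, coef, expo)
}

#' Construct a polynomial from raw term data
#'
#' Accepts arbitrary integer coefficients and exponents and returns the
#' canonical representative modulo `x_i^p - x_i` (exponents folded below
#' `p`, coefficients reduced mod `p`, zero terms dropped, duplicate
#' monomials merged).
#'
#' @param coef integer vector of term coefficients.
#' @param expo integer matrix, one row per term, `nvars` columns.
#' @param p prime field order.
#' @param nvars number of variables `x1..xn`.
#' @return An `fpoly` in canonical form.
#' @examples
#' fp_make(1, matrix(2, 1, 1), p = 2, nvars = 1)  # x1^2 -> x1
#' @export
fp_make <- function(coef, expo, p, nvars) {
  p <- as_field_p(p)
  nvars <- as.integer(nvars)
  if (is.null(dim(expo))) expo <- matrix(as.integer(expo), ncol = nvars)
  stopifnot(ncol(expo) == nvars, nrow(expo) == length(coef))
  fp_canon_terms(p, nvars, coef, expo)
}

#' @rdname fp_make
#' @export
fp_zero <- function(p, nvars) {
  p <- as_field_p(p)
  new_fpoly(p, as.integer(nvars), integer(0), matrix(0L, 0L, as.integer(nvars)))
}

#' @rdname fp_make
#' @param value constant value in `0..p-1`.
#' @export
fp_const <- function(value, p, nvars) {
  fp_make(as.integer(value), matrix(0L, 1L, as.integer(nvars)), p, nvars)
}

#' @rdname fp_make
#' @param i variable index in `1..nvars`.
#' @export
fp_var <- function(i, p, nvars) {
  nvars <- as.integer(nvars)
  i <- as.integer(i)
  stopifnot(i >= 1L, i <= nvars)
  e <- matrix(0L, 1L, nvars)
  e[1L, i] <- 1L
  fp_make(1L, e, p, nvars)
}

#' Reduce a polynomial to canonical form
#'
#' Idempotent: polynomials built by the package constructors are already
#' canonical, so this mostly matters when term data were assembled by
#' hand. The canonical form is the unique representative modulo the ideal
#' `(x_i^p - x_i)`; syntactic equality of canonical forms is equivalent
#' to equality as functions on F_p^n.
#'
#' @param x an `fpoly` or a [pds].
#' @return Object of the same class in canonical form.
#' @export
canonicalize <- function(x) UseMethod("canonicalize")

#' @export
canonicalize.fpoly <- function(x) {
  fp_canon_terms(x$p, x$nvars, x$coef, x$expo)
}

#' @export
canonicalize.pds <- function(x) {
  x$functions <- lapply(x$functions, canonicalize)
  x
}

fp_nterms <- function(f) length(f$coef)

fp_is_zero <- function(f) length(f$coef) == 0L

fp_is_constant <- function(f) {
  length(f$coef) == 0L || (length(f$coef) == 1L && all(f$expo == 0L))
}

fp_constant_value <- function(f) {
  if (length(f$coef) == 0L) 0L else f$coef[[1L]]
}

#' Support of a polynomial
#'
#' Indices of the variables that occur in the canonical form. Because the
#' representation is canonical, this is exactly the set of variables the
#' underlying function depends on.
#'
#' @param f an `fpoly`.
#' @return Integer vector of variable indices (sorted).
#' @export
fp_support <- function(f) {
  if (length(f$coef) == 0L) return(integer(0))
  which(colSums(f$expo > 0L) > 0L)
}

stopifnot_same_ring <- function(a, b) {
  if (a$p != b$p || a$nvars != b$nvars) {
    stop("polynomials live in different rings (p or nvars differ)")
  }
}

#' Polynomial ring arithmetic
#'
#' Exact addition, subtraction, negation, multiplication and small powers
#' in F_p[x1..xn] modulo the field equations; every result is canonical.
#'
#' @param a,b `fpoly` objects over the same field and variable set.
#' @return An `fpoly`.
#' @export
fp_add <- function(a, b) {
  stopifnot_same_ring(a, b)
  fp_canon_terms(a$p, a$nvars, c(a$coef, b$coef), rbind(a$expo, b$expo))
}

#' @rdname fp_add
#' @export
fp_sub <- function(a, b) {
  stopifnot_same_ring(a, b)
  fp_canon_terms(a$p, a$nvars, c(a$coef, -b$coef), rbind(a$expo, b$expo))
}

#' @rdname fp_add
#' @export
fp_neg <- function(a) {
  fp_canon_terms(a$p, a$nvars, -a$coef, a$expo)
}

#' @rdname fp_add
#' @export
fp_mul <- function(a, b) {
  stopifnot_same_ring(a, b)
  ta <- length(a$coef)
  tb <- length(b$coef)
  if (ta == 0L || tb == 0L) return(fp_zero(a$p, a$nvars))
  ia <- rep(seq_len(ta), each = tb)
  ib <- rep(seq_len(tb), times = ta)
  coef <- (a$coef[ia] * b$coef[ib]) %% a$p
  expo <- a$expo[ia, , drop = FALSE] + b$expo[ib, , drop = FALSE]
  fp_canon_terms(a$p, a$nvars, coef, expo)
}

#' @rdname fp_add
#' @param e non-negative integer exponent.
#' @export
fp_pow <- function(a, e) {
  e <- as.integer(e)
  stopifnot(e >= 0L)
  out <- fp_const(1L, a$p, a$nvars)
  while (e > 0L) {
    out <- fp_mul(out, a)
    e <- e - 1L
  }
  out
}

#' Exact equality of polynomials as functions
#'
#' Canonical forms are unique per function, so equality of term data
#' decides functional equality.
#'
#' @param a,b `fpoly` objects.
#' @return `TRUE` or `FALSE`.
#' @export
fp_equal <- function(a, b) {
  a <- canonicalize(a)
  b <- canonicalize(b)
  a$p == b$p && a$nvars == b$nvars &&
    identical(a$coef, b$coef) && identical(unname(a$expo), unname(b$expo))
}

#' Evaluate a polynomial
#'
#' `fp_eval` evaluates at one state; `fp_eval_states` is vectorized over
#' the rows of a state matrix (used heavily by the brute-force oracles
#' and the phase-space builder).
#'
#' @param f an `fpoly`.
#' @param state integer vector of length `nvars`, entries in `0..p-1`.
#' @return Value(s) in `0..p-1`.
#' @export
fp_eval <- function(f, state) {
  fp_eval_states(f, matrix(as.integer(state), nrow = 1L))[[1L]]
}

#' @rdname fp_eval
#' @param states integer matrix, one state per row.
#' @export
fp_eval_states <- function(f, states) {
  if (is.null(dim(states))) states <- matrix(as.integer(states), ncol = f$nvars)
  if (ncol(states) != f$nvars) stop("state dimension mismatch: expected ", f$nvars)
  m <- nrow(states)
  p <- f$p
  if (length(f$coef) == 0L) return(integer(m))
  acc <- integer(m)
  for (t in seq_along(f$coef)) {
    v <- rep.int(f$coef[[t]], m)
    et <- f$expo[t, ]
    for (j in which(et > 0L)) {
      v <- (v * states[, j]^et[[j]]) %% p
    }
    acc <- (acc + v) %% p
  }
  as.integer(acc)
}

#' Partially evaluate: substitute field values for some variables
#'
#' Replaces `x[idx[k]]` by the constant `vals[k]`; the result still lives
#' in the full `nvars`-variable ring (the substituted variables simply no
#' longer occur).
#'
#' @param f an `fpoly`.
#' @param idx integer vector of variable indices.
#' @param vals integer vector of values in `0..p-1`, same length as `idx`.
#' @return An `fpoly`.
#' @export
fp_subst_values <- function(f, idx, vals) {
  t <- length(f$coef)
  if (t == 0L || length(idx) == 0L) return(f)
  p <- f$p
  coef <- f$coef
  expo <- f$expo
  for (k in seq_along(idx)) {
    e <- expo[, idx[[k]]]
    coef <- (coef * as.integer(vals[[k]])^e) %% p
    expo[, idx[[k]]] <- 0L
  }
  fp_canon_terms(p, f$nvars, coef, expo)
}

#' Substitute polynomials for every variable
#'
#' Computes `f(g1, ..., gn)` where `glist[[j]]` replaces `x_j`. All
#' polynomials must share the field; the `glist` polynomials determine
#' the variable set of the result. Canonical reduction is applied after
#' every product so intermediate degrees never exceed `p - 1` per
#' variable.
#'
#' @param f an `fpoly` with `nvars = length(glist)`.
#' @param glist list of `fpoly` over a common ring.
#' @return An `fpoly` in the ring of the `glist` entries.
#' @export
fp_subst_polys <- function(f, glist) {
  stopifnot(length(glist) == f$nvars)
  p <- f$p
  nv_out <- glist[[1L]]$nvars
  if (length(f$coef) == 0L) return(fp_zero(p, nv_out))
  pow_cache <- vector("list", f$nvars)
  get_pow <- function(j, e) {
    if (is.null(pow_cache[[j]])) pow_cache[[j]] <<- list()
    key <- as.character(e)
    if (is.null(pow_cache[[j]][[key]])) {
      pow_cache[[j]][[key]] <- fp_pow(glist[[j]], e)
    }
    pow_cache[[j]][[key]]
  }
  acc <- fp_zero(p, nv_out)
  for (t in seq_along(f$coef)) {
    term <- fp_const(f$coef[[t]], p, nv_out)
    et <- f$expo[t, ]
    for (j in which(et > 0L)) {
      term <- fp_mul(term, get_pow(j, et[[j]]))
      if (fp_is_zero(term)) break
    }
    acc <- fp_add(acc, term)
  }
  acc
}

#' @export
format.fpoly <- function(x, ...) {
  if (length(x$coef) == 0L) return("0")
  terms <- vapply(seq_along(x$coef), function(t) {
    e <- x$expo[t, ]
    vars <- which(e > 0L)
    mono <- vapply(vars, function(j) {
      if (e[[j]] == 1L) paste0("x", j) else paste0("x", j, "^", e[[j]])
    }, character(1))
    c0 <- x$coef[[t]]
    if (length(mono) == 0L) return(as.character(c0))
    if (c0 == 1L) paste(mono, collapse = "*") else paste(c(c0, mono), collapse = "*")
  }, character(1))
  paste(terms, collapse = " + ")
}

#' @export
print.fpoly <- function(x, ...) {
  cat(sprintf("<fpoly over F_%d in %d vars> %s\n", x$p, x$nvars, format(x)))
  invisible(x)
}
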