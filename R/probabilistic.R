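# exact rationals on doubles (integer-valued; exact below 2^53),
# reduced with gcd -- keeps probabilistic graph weights exact
rat_gcd <- function(a, b) {
  a <- abs(a)
  b <- abs(b)
  while (b > 0) {
    t <- a %% b
    a <- b
    b <- t
  }
  a
}

rat_reduce <- function(num, den) {
  if (den == 0) stop("zero denominator")
  g <- rat_gcd(num, den)
  if (g == 0) return(c(0, 1))
  c(num / g, den / g)
}

rat_mul <- function(a, b) rat_reduce(a[1] * b[1], a[2] * b[2])

rat_add <- function(a, b) rat_reduce(a[1] * b[2] + b[1] * a[2], a[2] * b[2])

# parse "1/3", "0.25", or a numeric into a reduced rational
parse_probability <- function(x) {
  if (is.numeric(x)) {
    s <- format(x, digits = 15, scientific = FALSE)
  } else {
    s <- trimws(as.character(x))
  }
  if (grepl("^[0-9]+\\s*/\\s*[0-9]+$", s)) {
    parts <- as.numeric(strsplit(s, "/")[[1L]])
    return(rat_reduce(parts[1], parts[2]))
  }
  if (grepl("^[0-9]*\\.?[0-9]+$", s)) {
    dot <- regexpr("\\.", s)
    if (dot < 0) return(rat_reduce(as.numeric(s), 1))
    dec <- nchar(s) - dot
    return(rat_reduce(as.numeric(sub("\\.", "", s)), 10^dec))
  }
  stop("cannot parse probability: ", s)
}

#' Probabilistic polynomial dynamical system
#'
#' Each coordinate `i` carries a nonempty list of candidate update
#' polynomials and a probability distribution over them; at every
#' synchronous time step each coordinate independently picks one of its
#' rules according to its distribution (the probabilistic Boolean network
#' update model). Probabilities are stored as exact rationals so
#' transition-graph weights are exact; when no distribution is given the
#' uniform one is assumed.
#'
#' @param functions list of length `n`; element `i` is a list of
#'   [fpoly] update rules for `x_i`.
#' @param probs optional list of probability vectors (numerics, or
#'   strings like `"1/3"`), one per coordinate, each summing to 1;
#'   `NULL` for uniform.
#' @param p prime field order (default from the first rule).
#' @return Object of class `ppds`.
#' @export
ppds <- function(functions, probs = NULL, p = NULL) {
  stopifnot(is.list(functions), length(functions) >= 1L)
  n <- length(functions)
  if (is.null(p)) p <- functions[[1L]][[1L]]$p
  p <- as_field_p(p)
  pr <- vector("list", n)
  for (i in seq_len(n)) {
    rules <- functions[[i]]
    if (!is.list(rules) || length(rules) == 0L) {
      stop("coordinate ", i, " needs a nonempty list of rules")
    }
    for (f in rules) {
      if (!inherits(f, "fpoly") || f$p != p || f$nvars != n) {
        stop("rule of coordinate ", i, " has wrong field or variable count")
      }
    }
    functions[[i]] <- lapply(rules, canonicalize)
    l <- length(rules)
    if (is.null(probs) || is.null(probs[[i]])) {
      pr[[i]] <- matrix(rep(c(1, l), l), ncol = 2, byrow = TRUE)  # uniform 1/l
      pr[[i]][, 1] <- 1
    } else {
      given <- probs[[i]]
      if (length(given) != l) {
        stop("coordinate ", i, ": ", length(given), " probabilities for ",
             l, " rules")
      }
      pr[[i]] <- unname(t(vapply(given, parse_probability, numeric(2))))
    }
    if (any(pr[[i]][, 1] <= 0)) {
      stop("coordinate ", i, ": probabilities must be in (0, 1]")
    }
    tot <- c(0, 1)
    for (r in seq_len(l)) tot <- rat_add(tot, pr[[i]][r, ])
    if (!(tot[1] == 1 && tot[2] == 1)) {
      stop("coordinate ", i, ": probabilities sum to ", tot[1], "/", tot[2],
           ", not 1")
    }
  }
  structure(list(functions = functions, probs = pr, p = p, nvars = n),
            class = "ppds")
}

#' @export
print.ppds <- function(x, ...) {
  cat(sprintf("<ppds over F_%d, %d variables>\n", x$p, x$nvars))
  for (i in seq_len(min(x$nvars, 8L))) {
    for (r in seq_along(x$functions[[i]])) {
      cat(sprintf("  f%d = %s  # %g/%g\n", i, format(x$functions[[i]][[r]]),
                  x$probs[[i]][r, 1], x$probs[[i]][r, 2]))
    }
  }
  if (x$nvars > 8L) cat("  ...\n")
  invisible(x)
}

#' All-transitions graph of a probabilistic system
#'
#' For every state, enumerates the successors reachable under some
#' choice of per-coordinate rules (choices independent across
#' coordinates) and weights each distinct successor with its total
#' probability — a product of per-coordinate rule probabilities, summed
#' over choices leading to the same state. Out-weights of every state
#' sum to exactly 1 (exact rational arithmetic). States can thus have
#' out-degree greater than one, unlike the deterministic phase space.
#'
#' @param pp a [ppds].
#' @param exhaustive_threshold refuse when `p^nvars` exceeds this.
#' @return Object of class `prob_phase_space`: data frame `edges` with
#'   columns `from`, `to` (digit strings), `num`, `den` (exact weight),
#'   `prob` (numeric), plus `p`, `nvars`.
#' @export
probabilistic_transition_graph <- function(pp, exhaustive_threshold = 2^20) {
  p <- pp$p
  n <- pp$nvars
  if (as.numeric(p)^n > exhaustive_threshold) {
    stop_refusal(paste0("state space too large for the all-transitions graph ",
                        "(p^n = ", as.numeric(p)^n,
                        "); use true_steady_states() instead"))
  }
  states <- all_states(p, n)
  # per coordinate and rule, values on all states
  vals <- lapply(seq_len(n), function(i) {
    lapply(pp$functions[[i]], fp_eval_states, states = states)
  })
  from <- character(0)
  to <- character(0)
  wnum <- numeric(0)
  wden <- numeric(0)
  for (r in seq_len(nrow(states))) {
    # aggregate per-coordinate value distributions
    per <- lapply(seq_len(n), function(i) {
      v <- vapply(vals[[i]], function(x) x[[r]], integer(1))
      agg <- list()
      for (k in seq_along(v)) {
        key <- as.character(v[[k]])
        cur <- agg[[key]]
        if (is.null(cur)) cur <- c(0, 1)
        agg[[key]] <- rat_add(cur, pp$probs[[i]][k, ])
      }
      agg
    })
    # cartesian product of per-coordinate outcomes
    succ <- list(list(state = integer(0), w = c(1, 1)))
    for (i in seq_len(n)) {
      nxt <- list()
      for (s in succ) {
        for (key in names(per[[i]])) {
          nxt[[length(nxt) + 1L]] <- list(
            state = c(s$state, as.integer(key)),
            w = rat_mul(s$w, per[[i]][[key]]))
        }
      }
      succ <- nxt
    }
    agg <- list()
    for (s in succ) {
      key <- state_to_string(s$state)
      cur <- agg[[key]]
      if (is.null(cur)) cur <- c(0, 1)
      agg[[key]] <- rat_add(cur, s$w)
    }
    fk <- state_to_string(states[r, ])
    for (key in names(agg)) {
      from <- c(from, fk)
      to <- c(to, key)
      wnum <- c(wnum, agg[[key]][1])
      wden <- c(wden, agg[[key]][2])
    }
  }
  edges <- data.frame(from = from, to = to, num = wnum, den = wden,
                      prob = wnum / wden, stringsAsFactors = FALSE)
  structure(list(edges = edges, p = p, nvars = n), class = "prob_phase_space")
}

#' True steady states of a probabilistic system
#'
#' The states that are time-invariant no matter which update rule is
#' chosen: `f_{i,j}(x) = x_i` for every coordinate `i` and every rule
#' `j`. Equivalently the intersection of the fixed-point sets over all
#' deterministic rule selections — but encoded directly as the union of
#' all equations `f_{i,j} - x_i = 0` in one system, solved algebraically,
#' so it scales to large `n` without enumerating rule combinations or
#' states.
#'
#' @param pp a [ppds].
#' @param solution_limit passed to [solve_system()].
#' @return Integer matrix of states, one per row.
#' @export
true_steady_states <- function(pp, solution_limit = 2^20) {
  n <- pp$nvars
  eqs <- list()
  for (i in seq_len(n)) {
    xi <- fp_var(i, pp$p, n)
    for (f in pp$functions[[i]]) {
      eqs[[length(eqs) + 1L]] <- fp_sub(f, xi)
    }
  }
  solve_system(eqs, p = pp$p, nvars = n, solution_limit = solution_limit)
}
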