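# Independent brute-force oracles. These deliberately avoid the package's
# evaluation/solver code paths: polynomials are evaluated by a naive
# term-by-term sum, state spaces by explicit enumeration, attractors by
# iterating the successor map. Slow but unarguable at small n.

# naive evaluation of one fpoly at one state (integer arithmetic)
naive_eval <- function(f, state) {
  if (length(f$coef) == 0L) return(0L)
  tot <- 0
  for (t in seq_along(f$coef)) {
    v <- f$coef[t]
    for (j in seq_len(f$nvars)) {
      e <- f$expo[t, j]
      if (e > 0L) v <- v * state[j]^e
    }
    tot <- tot + v
  }
  as.integer(tot %% f$p)
}

naive_apply <- function(system, state) {
  vapply(system$functions, naive_eval, integer(1), state = state)
}

# all states of F_p^n, own enumeration (row order irrelevant to oracles)
enum_states <- function(p, n) {
  g <- do.call(expand.grid, rep(list(0:(p - 1L)), n))
  m <- as.matrix(g[, rev(seq_len(n)), drop = FALSE])
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

skey <- function(state) paste(state, collapse = "")

# successor row-index vector of the full state space
brute_successors <- function(system) {
  states <- enum_states(system$p, system$nvars)
  keys <- apply(states, 1L, skey)
  lookup <- seq_len(nrow(states))
  names(lookup) <- keys
  succ <- vapply(seq_len(nrow(states)), function(r) {
    lookup[[skey(naive_apply(system, states[r, ]))]]
  }, integer(1))
  list(states = states, keys = keys, succ = succ)
}

brute_fixed_points <- function(system) {
  bs <- brute_successors(system)
  sort(bs$keys[bs$succ == seq_along(bs$succ)])
}

# canonical description of one orbit: "period:minkey"
orbit_desc <- function(keys) paste0(length(keys), ":", min(keys))

# all attractors with exact period <= m, as a sorted character vector of
# "period:lexicographically-smallest-state" descriptors
brute_attractors <- function(system, m = Inf) {
  bs <- brute_successors(system)
  N <- length(bs$succ)
  # x := succ^K(x) for some K >= N, by repeated squaring of the map;
  # after that many steps every state sits on a cycle
  f <- bs$succ
  x <- seq_len(N)
  k <- N
  while (k > 0L) {
    if (k %% 2L == 1L) x <- f[x]
    f <- f[f]
    k <- k %/% 2L
  }
  cyc_nodes <- sort(unique(x))
  seen <- rep(FALSE, N)
  out <- character(0)
  for (s in cyc_nodes) {
    if (seen[s]) next
    orbit <- s
    v <- bs$succ[s]
    while (v != s) {
      orbit <- c(orbit, v)
      v <- bs$succ[v]
    }
    seen[orbit] <- TRUE
    if (length(orbit) <= m) out <- c(out, orbit_desc(bs$keys[orbit]))
  }
  sort(out)
}

# cycle_set -> the same canonical descriptor form
cycle_set_desc <- function(cs, include_steady = TRUE) {
  out <- character(0)
  if (include_steady && nrow(cs$steady_states)) {
    out <- apply(cs$steady_states, 1L, function(s) paste0("1:", skey(s)))
  }
  for (cy in cs$cycles) {
    out <- c(out, orbit_desc(apply(cy$states, 1L, skey)))
  }
  sort(out)
}

# one sweep of naive sequential updating
naive_sequential_sweep <- function(system, schedule, state) {
  for (i in schedule) state[i] <- naive_eval(system$functions[[i]], state)
  state
}

# random Boolean expression tree plus an R-level evaluator, for parser
# fidelity tests
random_bool_expr <- function(nvars, depth = 3L) {
  if (depth == 0L || stats::runif(1) < 0.3) {
    return(paste0("x", sample.int(nvars, 1L)))
  }
  op <- sample(c("AND", "OR", "NOT"), 1L)
  if (op == "NOT") {
    return(paste0("NOT (", random_bool_expr(nvars, depth - 1L), ")"))
  }
  paste0("(", random_bool_expr(nvars, depth - 1L), ") ", op, " (",
         random_bool_expr(nvars, depth - 1L), ")")
}

eval_bool_expr <- function(expr, state) {
  e <- gsub("NOT", "!", expr)
  e <- gsub("AND", "&", e)
  e <- gsub("OR", "|", e)
  for (j in rev(seq_along(state))) {
    e <- gsub(paste0("x", j, "\\b"), as.character(state[j] == 1L), e)
  }
  as.integer(eval(parse(text = e)))
}

# a concrete 3-variable Boolean system with one steady state (000) and
# one 3-cycle (010) -> (111) -> (011) -> (010); reconstructed by
# interpolating a full transition table with exactly these attractors
# (the remaining four states all map to the steady state). Synthetic
# stand-in used as the small worked example across tests.
example3 <- function() {
  nxt <- list("000" = "000", "010" = "111", "111" = "011", "011" = "010",
              "001" = "000", "100" = "000", "101" = "000", "110" = "000")
  states <- enum_states(2L, 3L)
  keys <- apply(states, 1L, skey)
  succ <- do.call(rbind, lapply(nxt[keys], function(s) as.integer(strsplit(s, "")[[1]])))
  pds(lapply(1:3, function(i) interpolate_table(succ[, i], 2L, 3L)), p = 2L)
}

# --- vectorized oracle (for the larger acceptance-scale checks) --------
# Same brute-force semantics as above, written against the raw term data
# so the whole state space is processed at once.

oracle_eval_states <- function(f, states) {
  m <- nrow(states)
  if (length(f$coef) == 0L) return(integer(m))
  acc <- numeric(m)
  for (t in seq_along(f$coef)) {
    v <- rep(as.numeric(f$coef[t]), m)
    for (j in seq_len(f$nvars)) {
      e <- f$expo[t, j]
      if (e > 0L) v <- v * states[, j]^e
    }
    acc <- acc + v
  }
  as.integer(acc %% f$p)
}

oracle_successors <- function(system) {
  states <- enum_states(system$p, system$nvars)
  keys <- apply(states, 1L, skey)
  nxt <- vapply(system$functions, oracle_eval_states, integer(nrow(states)),
                states = states)
  succ <- match(apply(nxt, 1L, skey), keys)
  list(states = states, keys = keys, succ = succ)
}

oracle_fixed_points <- function(system) {
  bs <- oracle_successors(system)
  sort(bs$keys[bs$succ == seq_along(bs$succ)])
}

oracle_attractors <- function(system, m = Inf) {
  bs <- oracle_successors(system)
  N <- length(bs$succ)
  f <- bs$succ
  x <- seq_len(N)
  k <- N
  while (k > 0L) {
    if (k %% 2L == 1L) x <- f[x]
    f <- f[f]
    k <- k %/% 2L
  }
  seen <- rep(FALSE, N)
  out <- character(0)
  for (s in sort(unique(x))) {
    if (seen[s]) next
    orbit <- s
    v <- bs$succ[s]
    while (v != s) {
      orbit <- c(orbit, v)
      v <- bs$succ[v]
    }
    seen[orbit] <- TRUE
    if (length(orbit) <= m) out <- c(out, orbit_desc(bs$keys[orbit]))
  }
  sort(out)
}
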