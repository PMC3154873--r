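#' Wiring diagram restricted to functional edges
#'
#' The wiring diagram (dependency graph) has one node per variable and a
#' directed edge `i -> j` exactly when `f_j` genuinely depends on `x_i`:
#' there is a witness state where changing only `x_i` changes the next
#' value of `x_j`. Because the update polynomials are canonical modulo
#' the field equations, genuine dependence coincides with `x_i` occurring
#' in the canonical form of `f_j`, so the diagram is read directly off
#' the polynomial support (the witness-search definition is kept as a
#' test oracle, see [edge_witness()]). Every edge in the diagram is
#' therefore functional; non-functional inputs never appear.
#'
#' For Boolean systems each edge is also classified by sign:
#' `"+"` (activation: `f_j` non-decreasing in `x_i`, increasing
#' somewhere), `"-"` (inhibition), or `"non-unate"` (both behaviours,
#' e.g. XOR inputs).
#'
#' @param system a [pds].
#' @param signs annotate edge signs (Boolean systems only; default
#'   exactly when `p == 2`).
#' @return Object of class `wiring_diagram`: list with `nvars` and
#'   `edges`, a data frame with columns `from`, `to`, `sign`.
#' @export
functional_wiring_diagram <- function(system, signs = system$p == 2L) {
  n <- system$nvars
  from <- integer(0)
  to <- integer(0)
  for (j in seq_len(n)) {
    supp <- fp_support(system$functions[[j]])
    from <- c(from, supp)
    to <- c(to, rep.int(j, length(supp)))
  }
  sign <- rep(NA_character_, length(from))
  if (signs && system$p == 2L) {
    sign <- vapply(seq_along(from), function(k) {
      edge_sign(system, from[k], to[k])
    }, character(1))
  }
  edges <- data.frame(from = from, to = to, sign = sign,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nvars = n, edges = edges), class = "wiring_diagram")
}

#' @export
print.wiring_diagram <- function(x, ...) {
  cat(sprintf("<wiring_diagram: %d nodes, %d functional edges>\n",
              x$nvars, nrow(x$edges)))
  for (k in seq_len(min(nrow(x$edges), 40L))) {
    e <- x$edges[k, ]
    cat(sprintf("  x%d -> x%d%s\n", e$from, e$to,
                if (is.na(e$sign)) "" else paste0("  [", e$sign, "]")))
  }
  if (nrow(x$edges) > 40L) cat("  ...\n")
  invisible(x)
}

#' Sign of a functional edge (Boolean systems)
#'
#' Classifies how `f_j` responds to `x_i` across every context of the
#' remaining variables, via the discrete derivative
#' `f_j(x_i = 1) - f_j(x_i = 0)`: `"+"` if non-negative in every context
#' and positive in at least one, `"-"` if non-positive everywhere and
#' negative somewhere, `"non-unate"` if both strict behaviours occur.
#' Only contexts over the support of `f_j` are enumerated, so the cost is
#' `2^(in-degree)`, not `2^n`.
#'
#' @param system a [pds] over F_2.
#' @param i,j edge `i -> j`; must be functional.
#' @return `"+"`, `"-"`, or `"non-unate"`.
#' @export
edge_sign <- function(system, i, j) {
  if (system$p != 2L) stop("edge signs are defined for Boolean systems (p = 2) only")
  f <- system$functions[[j]]
  supp <- fp_support(f)
  if (!(i %in% supp)) stop("edge x", i, " -> x", j, " is not functional")
  g0 <- fp_subst_values(f, i, 0L)
  g1 <- fp_subst_values(f, i, 1L)
  ctx <- setdiff(supp, i)
  grid <- all_states(2L, length(ctx))
  states <- matrix(0L, nrow(grid), system$nvars)
  if (length(ctx)) states[, ctx] <- grid
  d <- fp_eval_states(g1, states) - fp_eval_states(g0, states)
  if (any(d > 0L) && any(d < 0L)) return("non-unate")
  if (any(d > 0L)) return("+")
  if (any(d < 0L)) return("-")
  stop("edge x", i, " -> x", j, " is not functional")  # unreachable on canonical input
}

#' Exhaustive witness search for edge functionality (oracle)
#'
#' Finds a state pair differing only in `x_i` whose successors differ in
#' coordinate `j`, by scanning all `p^n` states. This is the definitional
#' check of functionality; the production path reads the canonical
#' support instead. Kept exported as the independent oracle used by the
#' test-suite.
#'
#' @param system a [pds] with a small state space.
#' @param i,j candidate edge `i -> j`.
#' @return A list `list(state_a, state_b)` witnessing functionality, or
#'   `NULL` when no witness exists.
#' @export
edge_witness <- function(system, i, j) {
  p <- system$p
  n <- system$nvars
  if (as.numeric(p)^n > 2^20) stop("state space too large for witness search")
  states <- all_states(p, n)
  fj <- system$functions[[j]]
  vals <- fp_eval_states(fj, states)
  for (r in seq_len(nrow(states))) {
    s <- states[r, ]
    for (b in 0:(p - 1L)) {
      if (b == s[i]) next
      s2 <- s
      s2[i] <- b
      if (vals[state_index(s2, p)] != vals[r]) {
        return(list(state_a = s, state_b = s2))
      }
    }
  }
  NULL
}

#' Enumerate all elementary circuits of a wiring diagram
#'
#' An elementary circuit is a closed directed path with all nodes
#' distinct; a self-loop is a length-1 circuit. Circuits are enumerated
#' by depth-first search rooted at each node over the subgraph of
#' not-smaller nodes (so each circuit is produced exactly once, anchored
#' at its minimum node) and returned sorted by length, then
#' lexicographic node sequence. Counts can grow exponentially, so
#' enumeration stops with a warning after `cap` circuits.
#'
#' @param wd a [functional_wiring_diagram()] result (or any object with
#'   `nvars` and an `edges` data frame with `from`/`to`).
#' @param cap maximum number of circuits to collect.
#' @return List of integer vectors (node sequences; the closing edge back
#'   to the first node is implicit). Attribute `truncated` is `TRUE` if
#'   the cap was hit.
#' @export
elementary_circuits <- function(wd, cap = 1e5) {
  n <- wd$nvars
  adj <- vector("list", n)
  for (k in seq_len(nrow(wd$edges))) {
    f <- wd$edges$from[k]
    adj[[f]] <- c(adj[[f]], wd$edges$to[k])
  }
  adj <- lapply(adj, function(v) sort(unique(v)))
  env <- new.env(parent = emptyenv())
  env$out <- list()
  env$truncated <- FALSE
  in_path <- logical(n)
  path <- integer(0)

  dfs <- function(v, root) {
    if (env$truncated) return(invisible(NULL))
    in_path[v] <<- TRUE
    path[length(path) + 1L] <<- v
    for (w in adj[[v]]) {
      if (w < root) next
      if (w == root) {
        if (length(env$out) >= cap) {
          env$truncated <- TRUE
          break
        }
        env$out[[length(env$out) + 1L]] <- path
      } else if (!in_path[w]) {
        dfs(w, root)
      }
    }
    in_path[v] <<- FALSE
    path <<- path[-length(path)]
    invisible(NULL)
  }
  for (root in seq_len(n)) {
    if (env$truncated) break
    dfs(root, root)
  }
  out <- env$out
  if (length(out) > 1L) {
    ord <- order(lengths(out),
                 vapply(out, function(v) paste(sprintf("%06d", v), collapse = "."),
                        character(1)))
    out <- out[ord]
  }
  if (env$truncated) {
    warning("circuit enumeration truncated at cap = ", cap)
    attr(out, "truncated") <- TRUE
  } else {
    attr(out, "truncated") <- FALSE
  }
  out
}

#' Functional circuits with signs (Boolean systems)
#'
#' Enumerates the elementary circuits of the functional wiring diagram
#' and signs each one: when every edge on the circuit is unate, the
#' circuit sign is the product of its edge signs (+1 positive feedback,
#' -1 negative feedback); circuits with a non-unate edge are left
#' unsigned. Positive functional circuits are of particular interest
#' because their presence is a necessary condition for multistationarity
#' (more than one steady state).
#'
#' A non-unate edge is activating in some contexts and inhibiting in
#' others, so a circuit through one has no single overall sign but *can*
#' realize positive feedback; such circuits are reported with `sign = NA`
#' and `positive_possible = TRUE`. The multistationarity condition
#' (at least two steady states implies a positive feedback circuit)
#' refers to `positive_possible`.
#'
#' @param system a [pds] over F_2.
#' @param cap circuit cap, as in [elementary_circuits()].
#' @return Data frame with columns `nodes` (list column of integer
#'   vectors), `length`, `sign` (+1, -1, or NA when unsigned),
#'   `positive` (sign is exactly +1), and `positive_possible` (positive,
#'   or unsigned because of a non-unate edge).
#' @export
functional_circuits <- function(system, cap = 1e5) {
  if (system$p != 2L) {
    stop("circuit sign analysis is implemented for Boolean systems (p = 2) only")
  }
  wd <- functional_wiring_diagram(system, signs = TRUE)
  circs <- elementary_circuits(wd, cap = cap)
  esign <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(wd$edges))) {
    esign[[paste(wd$edges$from[k], wd$edges$to[k])]] <- wd$edges$sign[k]
  }
  sgn <- vapply(circs, function(nodes) {
    ss <- vapply(seq_along(nodes), function(t) {
      a <- nodes[t]
      b <- nodes[if (t == length(nodes)) 1L else t + 1L]
      esign[[paste(a, b)]]
    }, character(1))
    if (any(ss == "non-unate")) return(NA_integer_)
    as.integer(prod(ifelse(ss == "+", 1L, -1L)))
  }, integer(1))
  out <- data.frame(length = lengths(circs), sign = sgn,
                    positive = !is.na(sgn) & sgn == 1L,
                    positive_possible = is.na(sgn) | sgn == 1L)
  out$nodes <- circs
  attr(out, "truncated") <- attr(circs, "truncated")
  out[, c("nodes", "length", "sign", "positive", "positive_possible")]
}
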