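test_that("wiring edges exist exactly where canonical support says", {
  # x1*(x1+1) vanishes on F_2: no edge despite the syntactic occurrence
  x1 <- fp_var(1, 2, 2)
  f <- pds(list(fp_mul(x1, fp_add(x1, fp_const(1, 2, 2))), fp_var(2, 2, 2)))
  wd <- functional_wiring_diagram(f)
  expect_false(any(wd$edges$to == 1L))

  sys <- pds(list(fp_var(2, 2, 2), fp_mul(fp_var(1, 2, 2), fp_var(2, 2, 2))))
  wd <- functional_wiring_diagram(sys)
  expect_equal(wd$edges[, c("from", "to")],
               data.frame(from = c(1L, 2L, 2L), to = c(2L, 1L, 2L)))

  const <- pds(list(fp_const(1, 2, 2), fp_const(0, 2, 2)))
  expect_equal(nrow(functional_wiring_diagram(const)$edges), 0L)
})

test_that("support-based edges match exhaustive witness search", {
  set.seed(103)
  for (rep in 1:10) {
    p <- sample(c(2L, 3L), 1)
    n <- sample(2:5, 1)
    sys <- random_sparse_pds(n, p = p, mean_in_degree = 1.5,
                             max_in_degree = min(3L, n), seed = 800 + rep)
    wd <- functional_wiring_diagram(sys, signs = FALSE)
    present <- paste(wd$edges$from, wd$edges$to)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        w <- edge_witness(sys, i, j)
        if (paste(i, j) %in% present) {
          expect_false(is.null(w))
          # the witness really flips coordinate j
          expect_true(naive_apply(sys, w$state_a)[j] != naive_apply(sys, w$state_b)[j])
        } else {
          expect_null(w)
        }
      }
    }
  }
})

test_that("elementary circuit enumeration is complete and deterministic", {
  ring3 <- list(nvars = 3L, edges = data.frame(from = c(1, 2, 3), to = c(2, 3, 1)))
  expect_equal(elementary_circuits(ring3), list(c(1L, 2L, 3L)),
               ignore_attr = TRUE)

  k3 <- expand.grid(from = 1:3, to = 1:3)
  k3 <- k3[k3$from != k3$to, ]
  circs <- elementary_circuits(list(nvars = 3L, edges = k3))
  expect_length(circs, 5L)                     # three 2-cycles, two 3-cycles
  expect_equal(lengths(circs), c(2L, 2L, 2L, 3L, 3L))

  loop <- list(nvars = 1L, edges = data.frame(from = 1, to = 1))
  expect_equal(elementary_circuits(loop), list(1L), ignore_attr = TRUE)

  # complete loopless digraph: sum over k of C(n,k) * (k-1)! circuits
  for (n in 3:6) {
    kn <- expand.grid(from = seq_len(n), to = seq_len(n))
    kn <- kn[kn$from != kn$to, ]
    want <- sum(vapply(2:n, function(k) choose(n, k) * factorial(k - 1), numeric(1)))
    expect_length(elementary_circuits(list(nvars = n, edges = kn)), want)
  }

  expect_warning(
    got <- elementary_circuits(list(nvars = 5L,
                                    edges = expand.grid(from = 1:5, to = 1:5)),
                               cap = 10),
    "truncated")
  expect_length(got, 10L)
})

test_that("edge signs classify activation, inhibition and non-unateness", {
  sys <- boolean_rules_to_pds(c("x2", "NOT x1", "x1 OR (NOT x1 AND NOT x2)"))
  expect_equal(edge_sign(sys, 2, 1), "+")
  expect_equal(edge_sign(sys, 1, 2), "-")
  xor <- boolean_rules_to_pds(c("(x1 AND NOT x2) OR (NOT x1 AND x2)", "x2"))
  expect_equal(edge_sign(xor, 1, 1), "non-unate")
  expect_equal(edge_sign(xor, 2, 1), "non-unate")
  expect_error(edge_sign(sys, 3, 1), "not functional")
  expect_error(edge_sign(pds_identity(3, 2), 1, 1), "p = 2")
})

test_that("edge signs match the exhaustive discrete derivative", {
  set.seed(107)
  for (rep in 1:10) {
    n <- sample(2:5, 1)
    sys <- random_sparse_pds(n, p = 2, mean_in_degree = 1.7,
                             max_in_degree = min(3L, n), seed = 900 + rep)
    wd <- functional_wiring_diagram(sys, signs = TRUE)
    states <- enum_states(2L, n)
    for (k in seq_len(nrow(wd$edges))) {
      i <- wd$edges$from[k]
      j <- wd$edges$to[k]
      diffs <- integer(0)
      for (r in which(states[, i] == 0L)) {
        s0 <- states[r, ]
        s1 <- s0
        s1[i] <- 1L
        diffs <- c(diffs, naive_eval(sys$functions[[j]], s1) -
                            naive_eval(sys$functions[[j]], s0))
      }
      want <- if (any(diffs > 0) && any(diffs < 0)) "non-unate"
              else if (any(diffs > 0)) "+" else "-"
      expect_equal(wd$edges$sign[k], want)
    }
  }
})

test_that("functional circuits carry the product of their edge signs", {
  self <- boolean_rules_to_pds("x1")
  fc <- functional_circuits(self)
  expect_equal(nrow(fc), 1L)
  expect_equal(fc$length, 1L)
  expect_true(fc$positive)

  neg2 <- boolean_rules_to_pds(c("NOT x2", "x1"))
  fc <- functional_circuits(neg2)
  expect_equal(fc$sign, -1L)
  expect_false(fc$positive)

  xor <- boolean_rules_to_pds(c("(x1 AND NOT x2) OR (NOT x1 AND x2)", "x1"))
  fc <- functional_circuits(xor)
  expect_true(any(is.na(fc$sign)))      # non-unate edge leaves circuits unsigned
})

test_that("multistationary Boolean networks contain a positive circuit", {
  set.seed(109)
  found <- 0L
  tries <- 0L
  while (found < 20L && tries < 400L) {
    tries <- tries + 1L
    n <- sample(3:7, 1)
    sys <- random_sparse_pds(n, p = 2, mean_in_degree = 1.7,
                             max_in_degree = min(3L, n), seed = 1000 + tries)
    if (length(brute_fixed_points(sys)) < 2L) next
    found <- found + 1L
    fc <- functional_circuits(sys)
    # non-unate edges act with either sign depending on context, so a
    # circuit through one can realize positive feedback
    expect_true(any(fc$positive_possible),
                label = paste("positive-capable circuit in multistationary net, seed",
                              1000 + tries))
  }
  expect_gte(found, 20L)
})
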