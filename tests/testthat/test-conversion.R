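test_that("Boolean operators map to their polynomial counterparts", {
  expect_true(fp_equal(parse_boolean("x1 AND x2", 2), parse_polynomial("x1*x2", 2, 2)))
  expect_true(fp_equal(parse_boolean("NOT x1", 1), parse_polynomial("x1 + 1", 2, 1)))
  f <- parse_boolean("(x1 OR x2) AND NOT x3", 3)
  states <- enum_states(2L, 3L)
  for (r in seq_len(nrow(states))) {
    s <- states[r, ]
    expect_identical(naive_eval(f, s),
                     as.integer((s[1] | s[2]) && !s[3]))
  }
})

test_that("Boolean conversion preserves truth tables for random expressions", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    expr <- random_bool_expr(n, depth = sample(1:4, 1))
    f <- parse_boolean(expr, n)
    states <- enum_states(2L, n)
    got <- vapply(seq_len(nrow(states)), function(r) naive_eval(f, states[r, ]),
                  integer(1))
    want <- vapply(seq_len(nrow(states)), function(r) eval_bool_expr(expr, states[r, ]),
                   integer(1))
    expect_identical(got, want)
  }
})

test_that("symbolic aliases and case-insensitive keywords parse identically", {
  a <- parse_boolean("x1 and not x2 or x3", 3)
  b <- parse_boolean("x1 & !x2 | x3", 3)
  d <- parse_boolean("x1 AND ~x2 OR x3", 3)
  expect_true(fp_equal(a, b))
  expect_true(fp_equal(a, d))
  expect_error(parse_boolean("x1 AND", 2), "unexpected end")
  expect_error(parse_boolean("x1 XOR x2", 2), "position")
})

table5 <- function() {
  # Boolean x1 (levels 0..1) driving three-level x2 (levels 0..2);
  # x1 keeps its own value
  logical_table(c(1, 2), list(c(0, 0, 0, 1, 1, 1), c(0, 1, 2, 1, 2, 2)))
}

test_that("multi-valued extension repeats the last defined row", {
  m <- extend_multivalued(table5(), p = 3)
  tt <- fp_truth_table(m$functions[[2]])
  # rows x1 = 0, 1, 2 of the next-state table of x2; the extension row
  # (x1 = 2) duplicates x1 = 1: medium, high, high
  expect_equal(tt, c(0L, 1L, 2L, 1L, 2L, 2L, 1L, 2L, 2L))
  expect_equal(tt[7:9], c(1L, 2L, 2L))
  expect_equal(attr(m, "max_levels"), c(1L, 2L))
  # x1's own extension clamps to its maximum level 1
  expect_equal(fp_truth_table(m$functions[[1]]), rep(c(0L, 0L, 0L, 1L, 1L, 1L, 1L, 1L, 1L)))
  expect_error(extend_multivalued(table5(), p = 2), "smaller")
})

test_that("extension is the identity when all variables already fill the field", {
  set.seed(13)
  n <- 3L
  p <- 3L
  outs <- lapply(1:n, function(i) sample(0:(p - 1), p^n, replace = TRUE))
  tab <- logical_table(rep(p - 1L, n), outs)
  m <- extend_multivalued(tab, p)
  for (i in 1:n) expect_equal(fp_truth_table(m$functions[[i]]), outs[[i]])
})

test_that("Boolean models extended to F_3 agree with the original on 0/1 states", {
  set.seed(17)
  for (rep in 1:5) {
    n <- sample(2:4, 1)
    bool_sys <- random_sparse_pds(n, p = 2, mean_in_degree = 1.5,
                                  max_in_degree = min(3L, n), seed = rep)
    outs <- lapply(1:n, function(i) fp_truth_table(bool_sys$functions[[i]]))
    ext <- extend_multivalued(logical_table(rep(1L, n), outs), p = 3)
    states <- enum_states(2L, n)
    for (r in seq_len(nrow(states))) {
      expect_equal(pds_evaluate(ext, states[r, ]),
                   naive_apply(bool_sys, states[r, ]))
    }
  }
})

test_that("artifact states (out-of-range levels) are flagged, not dropped", {
  ml <- c(1L, 2L)
  expect_equal(flag_artifact_states(rbind(c(0, 2), c(2, 0), c(1, 2)), ml),
               c(FALSE, TRUE, FALSE))
})

test_that("sequential sweeps collapse to the expected synchronous system", {
  idsys <- pds_identity(2, 3)
  expect_true(pds_equal(sequential_compose(idsys, c(2, 3, 1)), idsys))

  sw <- pds(list(fp_var(2, 2, 2), fp_var(1, 2, 2)))
  s12 <- sequential_compose(sw, c(1, 2))
  s21 <- sequential_compose(sw, c(2, 1))
  # updating x1 first: x1' = x2, then x2' = x1' = x2
  expect_true(pds_equal(s12, pds(list(fp_var(2, 2, 2), fp_var(2, 2, 2)))))
  expect_true(pds_equal(s21, pds(list(fp_var(1, 2, 2), fp_var(1, 2, 2)))))
  expect_error(sequential_compose(sw, c(1, 1)), "permutation")

  # the collapsed system reproduces stepwise sequential simulation
  set.seed(41)
  for (rep in 1:8) {
    n <- sample(2:5, 1)
    sys <- random_sparse_pds(n, p = 2, mean_in_degree = 1.5,
                             max_in_degree = min(3L, n), seed = 100 + rep)
    sched <- sample.int(n)
    collapsed <- sequential_compose(sys, sched)
    states <- enum_states(2L, n)
    for (r in seq_len(nrow(states))) {
      expect_equal(pds_evaluate(collapsed, states[r, ]),
                   naive_sequential_sweep(sys, sched, states[r, ]))
    }
  }
})

test_that("fixed points are invariant under the update schedule", {
  set.seed(43)
  for (rep in 1:12) {
    n <- sample(3:8, 1)
    p <- sample(c(2L, 3L), 1)
    sys <- random_sparse_pds(n, p = p, mean_in_degree = 1.7,
                             max_in_degree = min(3L, n), seed = 200 + rep)
    sched <- sample.int(n)
    fp_sync <- apply(steady_states(sys), 1L, skey)
    fp_seq <- apply(steady_states(sequential_compose(sys, sched)), 1L, skey)
    expect_identical(sort(fp_sync), sort(fp_seq))
  }
})

test_that("continuity validation detects level jumps", {
  # three-level variable dropping from 2 straight to 0 is discontinuous
  jump <- pds(list(interpolate_table(c(0, 0, 0), 3, 1)))
  expect_false(pds_is_continuous(jump))
  expect_true(pds_is_continuous(pds_identity(3, 2)))
  # Boolean systems are always continuous
  set.seed(3)
  sys <- random_sparse_pds(4, p = 2, seed = 9)
  expect_true(pds_is_continuous(sys))
})
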