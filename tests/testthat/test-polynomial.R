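test_that("canonical reduction folds field equations and characteristic", {
  # x1^2 = x1 on F_2
  expect_equal(format(fp_make(1, matrix(2, 1, 1), p = 2, nvars = 1)), "x1")
  # x1 + x1 = 0 in characteristic 2
  expect_true(fp_is_zero(fp_make(c(1, 1), rbind(1, 1), p = 2, nvars = 1)))
  # x2^4 = x2^2 on F_3
  f <- fp_make(1, matrix(c(0, 4), 1, 2), p = 3, nvars = 2)
  expect_equal(format(f), "x2^2")
  # x1*(x1+1) vanishes identically on F_2
  x1 <- fp_var(1, 2, 1)
  expect_true(fp_is_zero(fp_mul(x1, fp_add(x1, fp_const(1, 2, 1)))))
})

test_that("canonicalization is idempotent and preserves the evaluation map", {
  set.seed(11)
  for (p in c(2L, 3L, 5L)) {
    for (rep in 1:10) {
      n <- sample(1:4, 1)
      nt <- sample(1:6, 1)
      raw_coef <- sample(-10:10, nt, replace = TRUE)
      raw_expo <- matrix(sample(0:7, nt * n, replace = TRUE), nt, n)
      f <- fp_make(raw_coef, raw_expo, p, n)
      expect_true(fp_equal(canonicalize(f), f))
      states <- enum_states(p, n)
      for (r in seq_len(nrow(states))) {
        v_raw <- 0
        for (t in seq_len(nt)) {
          term <- raw_coef[t]
          for (j in seq_len(n)) term <- term * states[r, j]^raw_expo[t, j]
          v_raw <- v_raw + term
        }
        expect_identical(fp_eval(f, states[r, ]), as.integer(v_raw %% p))
      }
    }
  }
})

test_that("evaluation matches direct substitution", {
  expect_equal(pds_evaluate(pds_identity(2, 2), c(1, 0)), c(1L, 0L))
  f <- pds(list(fp_var(2, 2, 2), fp_mul(fp_var(1, 2, 2), fp_var(2, 2, 2))))
  expect_equal(pds_evaluate(f, c(1, 0)), c(0L, 0L))
  expect_error(pds_evaluate(f, c(1, 0, 1)), "length")
  expect_error(pds_evaluate(f, c(2, 0)), "0\\.\\.1")
})

test_that("interpolation realizes Boolean gates and inverts tabulation", {
  expect_equal(format(interpolate_table(c(0, 0, 0, 1), 2, 2)), "x1*x2")
  or <- interpolate_table(c(0, 1, 1, 1), 2, 2)
  expect_true(fp_equal(or, parse_polynomial("x1 + x2 + x1*x2", 2, 2)))
  expect_error(interpolate_table(c(0, 1, 1), 2, 2), "incomplete")

  set.seed(7)
  for (p in c(2L, 3L)) {
    for (rep in 1:8) {
      n <- sample(1:4, 1)
      g <- fp_make(sample(0:(p - 1), 3, replace = TRUE),
                   matrix(sample(0:(p - 1), 3 * n, replace = TRUE), 3, n), p, n)
      tt <- fp_truth_table(g)
      expect_true(fp_equal(interpolate_table(tt, p, n), g))
    }
  }
})

test_that("the multi-level table polynomial reproduces every printed cell", {
  # two-variable model: Boolean x1 drives a three-level x2 (levels
  # low/medium/high = 0/1/2); the x1 = 2 row repeats the x1 = 1 row
  vals <- c(0, 1, 2,  # x1 absent:  low, medium, high stay
            1, 2, 2,  # x1 present: medium, high, high
            1, 2, 2)  # extension row, same as x1 present
  f <- interpolate_table(vals, p = 3, nvars = 2)
  expect_equal(fp_truth_table(f), as.integer(vals))
  # "x1 present, x2 low" updates x2 to medium
  expect_equal(fp_eval(f, c(1, 0)), 1L)
})

test_that("composition agrees with iterated application", {
  # negation is an involution
  neg <- pds(list(fp_add(fp_var(1, 2, 1), fp_const(1, 2, 1))))
  expect_true(pds_equal(pds_compose(neg, 2), pds_identity(2, 1)))
  expect_true(pds_equal(pds_compose(pds_identity(3, 2), 5), pds_identity(3, 2)))
  # swapping twice is the identity
  sw <- pds(list(fp_var(2, 2, 2), fp_var(1, 2, 2)))
  expect_true(pds_equal(pds_compose(sw, 2), pds_identity(2, 2)))
  expect_error(pds_compose(sw, 0), "positive")

  set.seed(23)
  for (p in c(2L, 3L, 5L)) {
    for (rep in 1:5) {
      n <- sample(2:4, 1)
      sys <- random_sparse_pds(n, p = p, mean_in_degree = 1.0,
                               max_in_degree = min(3L, n),
                               seed = sample.int(1e6, 1))
      m <- sample(1:4, 1)
      cm <- pds_compose(sys, m)
      states <- enum_states(p, n)
      for (r in seq_len(nrow(states))) {
        x <- states[r, ]
        for (k in seq_len(m)) x <- naive_apply(sys, x)
        expect_equal(pds_evaluate(cm, states[r, ]), x)
      }
    }
  }
})

test_that("polynomial parser round-trips the printed form and flags errors", {
  set.seed(5)
  for (p in c(2L, 3L, 5L)) {
    for (rep in 1:6) {
      n <- sample(1:4, 1)
      f <- fp_make(sample(0:(p - 1), 4, replace = TRUE),
                   matrix(sample(0:(p - 1), 4 * n, replace = TRUE), 4, n), p, n)
      expect_true(fp_equal(parse_polynomial(format(f), p, n), f))
    }
  }
  expect_true(fp_equal(parse_polynomial("2*x1^2 - x2 + 4", 3, 2),
                       fp_make(c(2, -1, 4), rbind(c(2, 0), c(0, 1), c(0, 0)), 3, 2)))
  expect_error(parse_polynomial("x1 +", 2, 2), "unexpected end")
  expect_error(parse_polynomial("x1 * * x2", 2, 2), "position")
  expect_error(parse_polynomial("x9", 2, 2), "out of range")
})
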