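test_that("solve_system returns exactly the rational roots", {
  expect_equal(solve_system(list(parse_polynomial("x1 + 1", 2, 1))),
               matrix(1L, 1, 1))
  sols <- solve_system(list(parse_polynomial("x1 + x2 + 1", 2, 2)))
  expect_equal(sols, rbind(c(0L, 1L), c(1L, 0L)))
  # x1*x2 = 1 with x2 = -x1 has no F_3 solution (2*x1^2 + 2 = 0, x1 + x2 = 0)
  eqs <- list(parse_polynomial("2*x1^2 + 2", 3, 2), parse_polynomial("x1 + x2", 3, 2))
  # confirm by brute force first
  states <- enum_states(3L, 2L)
  brute <- states[apply(states, 1, function(s) {
    all(vapply(eqs, naive_eval, integer(1), state = s) == 0L)
  }), , drop = FALSE]
  expect_equal(nrow(brute), 0L)
  expect_equal(nrow(solve_system(eqs)), 0L)
  # inconsistent ring dimensions are rejected
  expect_error(solve_system(list(parse_polynomial("x1", 2, 1),
                                 parse_polynomial("x1 + x2", 2, 2))),
               "inconsistent")
})

test_that("solve_system agrees with exhaustive root search on random systems", {
  set.seed(71)
  for (rep in 1:20) {
    p <- sample(c(2L, 3L), 1)
    n <- sample(2:6, 1)
    eqs <- lapply(seq_len(sample(1:4, 1)), function(k) {
      fp_make(sample(0:(p - 1), 3, replace = TRUE),
              matrix(sample(0:(p - 1), 3 * n, replace = TRUE), 3, n), p, n)
    })
    states <- enum_states(p, n)
    brute <- states[apply(states, 1, function(s) {
      all(vapply(eqs, naive_eval, integer(1), state = s) == 0L)
    }), , drop = FALSE]
    got <- solve_system(eqs, p = p, nvars = n)
    expect_identical(sort(apply(got, 1, skey)), sort(apply(brute, 1, skey)))
  }
})

test_that("steady states solve f(x) = x completely", {
  expect_equal(nrow(steady_states(pds_identity(2, 3))), 8L)
  neg <- pds(lapply(1:3, function(i) {
    fp_add(fp_var(i, 2, 3), fp_const(1, 2, 3))
  }))
  expect_equal(nrow(steady_states(neg)), 0L)

  set.seed(73)
  for (rep in 1:15) {
    p <- sample(c(2L, 3L), 1)
    n <- if (p == 2L) sample(3:10, 1) else sample(3:7, 1)
    sys <- random_sparse_pds(n, p = p, mean_in_degree = 1.7,
                             max_in_degree = min(3L, n), seed = 300 + rep)
    got <- apply(steady_states(sys), 1, skey)
    expect_identical(sort(got), brute_fixed_points(sys))
  }
})

test_that("limit cycles are grouped into orbits with exact periods", {
  neg <- pds(list(fp_add(fp_var(1, 2, 1), fp_const(1, 2, 1))))
  cs <- limit_cycles(neg, 2)
  expect_equal(nrow(cs$steady_states), 0L)
  expect_length(cs$cycles, 1L)
  expect_equal(cs$cycles[[1]]$period, 2L)
  expect_equal(apply(cs$cycles[[1]]$states, 1, skey), c("0", "1"))

  rot <- pds(list(fp_var(3, 2, 3), fp_var(1, 2, 3), fp_var(2, 2, 3)))
  cs <- limit_cycles(rot, 3)
  expect_equal(apply(cs$steady_states, 1, skey), c("000", "111"))
  expect_length(cs$cycles, 2L)
  expect_equal(vapply(cs$cycles, function(cy) cy$period, integer(1)), c(3L, 3L))
  expect_identical(cycle_set_desc(cs), brute_attractors(rot, 3))
  expect_error(limit_cycles(rot, 0), ">= 1")
})

test_that("a worked 3-variable example has one steady state and one 3-cycle", {
  f <- example3()
  # searching length 1 and 2 finds only the steady state
  cs1 <- limit_cycles(f, 1)
  expect_equal(apply(cs1$steady_states, 1, skey), "000")
  expect_length(cs1$cycles, 0L)
  cs2 <- limit_cycles(f, 2)
  expect_length(cs2$cycles, 0L)
  # length 3 reveals the cycle through (010), (111), (011)
  cs3 <- limit_cycles(f, 3)
  expect_length(cs3$cycles, 1L)
  expect_equal(cs3$cycles[[1]]$period, 3L)
  expect_setequal(apply(cs3$cycles[[1]]$states, 1, skey), c("010", "111", "011"))
  # longer searches add nothing new (all exact periods are 1 or 3)
  expect_identical(cycle_set_desc(limit_cycles(f, 5)), cycle_set_desc(cs3))
})

test_that("limit_cycles at length 1 equals steady_states", {
  set.seed(79)
  for (rep in 1:6) {
    sys <- random_sparse_pds(sample(3:7, 1), p = 2, seed = 400 + rep)
    cs <- limit_cycles(sys, 1)
    expect_length(cs$cycles, 0L)
    expect_identical(apply(cs$steady_states, 1, skey),
                     apply(steady_states(sys), 1, skey))
  }
})

test_that("attractor search matches brute force on random systems", {
  set.seed(83)
  for (rep in 1:12) {
    p <- sample(c(2L, 3L), 1)
    n <- if (p == 2L) sample(3:9, 1) else sample(3:6, 1)
    sys <- random_sparse_pds(n, p = p, mean_in_degree = 1.7,
                             max_in_degree = min(3L, n), seed = 500 + rep)
    m <- sample(2:4, 1)
    expect_identical(cycle_set_desc(limit_cycles(sys, m)),
                     brute_attractors(sys, m))
  }
})

test_that("the solver scales to implanted fixed points far beyond enumeration", {
  set.seed(89)
  net <- random_sparse_pds(120, p = 2, mean_in_degree = 1.7, seed = 97)
  planted <- matrix(sample(0:1, 4 * 120, replace = TRUE), 4, 120)
  net <- implant_fixed_points(net, planted)
  found <- steady_states(net)
  expect_true(all(apply(planted, 1, skey) %in% apply(found, 1, skey)))
  # every reported state verifies f(x) = x
  expect_true(all(pds_evaluate_states(net, found) == found))
})

test_that("underdetermined systems hit the solution limit guard", {
  expect_error(steady_states(pds_identity(2, 40)), "solution_limit")
})

test_that("the exhaustive phase space agrees with the algebraic route", {
  neg1 <- pds(list(fp_add(fp_var(1, 2, 1), fp_const(1, 2, 1))))
  ps <- build_phase_space(neg1)
  expect_equal(nrow(ps$states), 2L)
  expect_equal(ps$succ, c(2L, 1L))
  expect_length(ps$attractors, 1L)

  id2 <- pds_identity(2, 2)
  ps <- build_phase_space(id2)
  expect_equal(ps$succ, 1:4)            # four self-loops
  expect_length(ps$attractors, 4L)      # four components of size one
  expect_equal(ps$component_sizes, rep(1L, 4))

  set.seed(97)
  for (rep in 1:8) {
    sys <- random_sparse_pds(sample(3:6, 1), p = 2, seed = 600 + rep)
    ps <- build_phase_space(sys)
    expect_identical(cycle_set_desc(phase_space_cycle_set(ps)),
                     brute_attractors(sys))
    # basin sizes partition the state space
    expect_equal(sum(ps$component_sizes), nrow(ps$states))
  }

  expect_error(build_phase_space(pds_identity(2, 25)),
               class = "polydyn_refusal")
})

test_that("trajectories end in a reported attractor", {
  tr <- trajectory(pds_identity(2, 2), c(1, 0))
  expect_equal(tr$type, "steady_state")
  expect_equal(nrow(tr$path), 1L)

  neg1 <- pds(list(fp_add(fp_var(1, 2, 1), fp_const(1, 2, 1))))
  tr <- trajectory(neg1, "0")
  expect_equal(apply(tr$path, 1, skey), c("0", "1"))
  expect_equal(tr$attractor$period, 2L)

  set.seed(101)
  for (rep in 1:8) {
    n <- sample(3:7, 1)
    sys <- random_sparse_pds(n, p = 2, seed = 700 + rep)
    start <- sample(0:1, n, replace = TRUE)
    tr <- trajectory(sys, start)
    # the last transient state maps into the attractor
    akeys <- apply(tr$attractor$states, 1, skey)
    if (nrow(tr$transient)) {
      last <- tr$transient[nrow(tr$transient), ]
      expect_true(skey(naive_apply(sys, last)) %in% akeys)
    }
    # the attractor shows up in the algebraic search at its own period
    cs <- limit_cycles(sys, tr$attractor$period)
    expect_true(orbit_desc(akeys) %in% cycle_set_desc(cs))
  }
})
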