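test_that("single updates follow sigma(Wx) componentwise", {
  pm1 <- dynamics_spec("pm1")
  expect_equal(rtn_step(diag(2), c(1L, -1L), pm1), c(1L, -1L))
  expect_equal(rtn_step(-diag(1), 1L, pm1), -1L)
  # h = (x2, -x1): hand evaluation of the quarter-turn coupling
  w <- matrix(c(0, 1, -1, 0), 2, 2, byrow = TRUE)
  expect_equal(rtn_step(w, c(1L, 1L), pm1), c(1L, -1L))
  # zero_one map: Heaviside with off state 0
  z <- dynamics_spec("zero_one")
  expect_equal(rtn_step(diag(2), c(1L, 0L), z), c(1L, 0L))
})

test_that("zero net inputs follow the chosen convention", {
  w <- matrix(0, 2, 2)  # every net input is zero
  x <- c(1L, -1L)
  expect_equal(rtn_step(w, x, dynamics_spec("pm1", zero_convention = "minus")),
               c(-1L, -1L))
  expect_equal(rtn_step(w, x, dynamics_spec("pm1", zero_convention = "plus")),
               c(1L, 1L))
  expect_equal(rtn_step(w, x, dynamics_spec("pm1",
                                            zero_convention = "keep_previous")),
               x)
  # quenched tie-breaks are fixed per matrix, keeping dynamics deterministic
  set.seed(1)
  wq <- with_tie_signs(w)
  dq <- dynamics_spec("pm1", zero_convention = "quenched_random")
  first <- rtn_step(wq, x, dq)
  for (i in 1:5) expect_identical(rtn_step(wq, x, dq), first)
  expect_equal(first, ifelse(attr(wq, "tie_signs") > 0, 1L, -1L))
})

test_that("continuous states under a step norm are coerced with a warning", {
  expect_warning(res <- rtn_step(diag(2), c(0.9, -0.2), dynamics_spec("pm1")),
                 "coerced")
  expect_equal(res, c(1L, -1L))
  expect_error(rtn_step(diag(2), c(1L, 1L, 1L), dynamics_spec("pm1")),
               "dimension mismatch")
})

test_that("attractors of canonical small systems are exact", {
  pm1 <- dynamics_spec("pm1")
  # identity fixes every state
  res <- iterate_to_attractor(diag(4), c(1L, -1L, 1L, 1L), pm1)
  expect_equal(res[c("outcome", "period", "transient")],
               list(outcome = "fixed_point", period = 1L, transient = 0L))
  # negation flips every state: a pure 2-cycle
  res <- iterate_to_attractor(-diag(3), c(1L, 1L, -1L), pm1)
  expect_equal(res[c("outcome", "period", "transient")],
               list(outcome = "cycle", period = 2L, transient = 0L))
  # quarter-turn coupling: hand iteration gives a 4-cycle
  w <- matrix(c(0, 1, -1, 0), 2, 2, byrow = TRUE)
  res <- iterate_to_attractor(w, c(1L, 1L), pm1, keep_attractor = TRUE)
  expect_equal(res$period, 4L)
  expect_equal(res$attractor,
               matrix(c(1L, 1L, 1L, -1L, -1L, -1L, -1L, 1L), 4, 2,
                      byrow = TRUE))
})

test_that("t_max exhaustion reports unresolved, never a wrong attractor", {
  w <- matrix(c(0, 1, -1, 0), 2, 2, byrow = TRUE)
  res <- iterate_to_attractor(w, c(1L, 1L),
                              dynamics_spec("pm1", t_max = 3))
  expect_equal(res$outcome, "unresolved")
  expect_true(is.na(res$period))
  expect_equal(res$steps_run, 3L)
})

test_that("discrete attractors are closed under one more update", {
  set.seed(20)
  pm1 <- dynamics_spec("pm1")
  for (i in 1:100) {
    w <- generate_matrix(ensemble_spec(6, k = 3))
    x0 <- random_initial_state(6, "pm1")
    res <- iterate_to_attractor(w, x0, pm1, keep_attractor = TRUE)
    expect_false(res$outcome == "unresolved")
    att <- res$attractor
    for (p in seq_len(res$period)) {
      nxt <- rtn_step(w, att[p, ], pm1)
      expect_equal(nxt, att[(p %% res$period) + 1L, ])
    }
  }
})

test_that("iterate agrees with the functional-graph census on every state", {
  set.seed(21)
  pm1 <- dynamics_spec("pm1")
  for (i in 1:50) {
    n <- sample(2:4, 1)
    w <- generate_matrix(ensemble_spec(n, k = sample(n, 1)))
    census <- oracle_census(w, "pm1")
    for (s in seq_len(nrow(census$states))) {
      res <- iterate_to_attractor(w, census$states[s, ], pm1)
      expect_equal(res$outcome, census$outcome[s])
      expect_equal(res$period, census$period[s])
      expect_equal(res$transient, census$transient[s])
    }
  }
})

test_that("pm1 trajectories are antisymmetric when inputs never vanish", {
  set.seed(22)
  pm1 <- dynamics_spec("pm1")
  for (i in 1:200) {
    w <- generate_matrix(ensemble_spec(7, k = 4,
                                       weight_scheme = "real_gaussian"))
    x0 <- random_initial_state(7, "pm1")
    # trajectory from -x0 is the negation of the trajectory from x0
    xa <- x0; xb <- -x0
    for (t in 1:10) {
      xa <- rtn_step(w, xa, pm1)
      xb <- rtn_step(w, xb, pm1)
      expect_equal(xb, -xa)
    }
    ra <- iterate_to_attractor(w, x0, pm1)
    rb <- iterate_to_attractor(w, -x0, pm1)
    expect_equal(ra$period, rb$period)
    expect_equal(ra$transient, rb$transient)
  }
})

test_that("a period-1 report means sigma(W x*) = x* exactly", {
  set.seed(23)
  pm1 <- dynamics_spec("pm1")
  found <- 0L
  for (i in 1:200) {
    w <- generate_matrix(ensemble_spec(5, k = 2))
    x0 <- random_initial_state(5, "pm1")
    res <- iterate_to_attractor(w, x0, pm1, keep_attractor = TRUE)
    if (res$outcome == "fixed_point") {
      found <- found + 1L
      expect_equal(rtn_step(w, res$attractor[1, ], pm1), res$attractor[1, ])
    }
  }
  expect_gt(found, 10)
})

test_that("continuous dynamics find fixed points and cycles within tolerance", {
  # self-activation with a steep sigmoid: corners are attracting
  dc <- dynamics_spec("pm1", norm = "sigmoid", steepness = 50)
  res <- iterate_to_attractor(diag(3), c(1, -1, 1), dc)
  expect_equal(res$outcome, "fixed_point")
  # a shallow self-repressor contracts to the interior fixed point at 0
  dshallow <- dynamics_spec("pm1", norm = "sigmoid", steepness = 0.01)
  res <- iterate_to_attractor(-diag(1), 1, dshallow, keep_attractor = TRUE)
  expect_equal(res$outcome, "fixed_point")
  expect_lt(abs(res$attractor[1, 1]), 0.01)
  # steep self-repression alternates between near-corner states: a 2-cycle
  res <- iterate_to_attractor(-diag(2), c(1, 1), dc)
  expect_equal(res$outcome, "cycle")
  expect_equal(res$period, 2L)
  # zero_one sigmoid stays in (0, 1)
  dz <- dynamics_spec("zero_one", norm = "sigmoid", steepness = 5)
  x <- rtn_step(diag(2), c(1, 0), dz)
  expect_true(all(x > 0 & x < 1))
})

test_that("steep sigmoids reproduce the sign dynamics, shallow ones need not", {
  set.seed(24)
  for (i in 1:20) {
    w <- generate_matrix(ensemble_spec(7, k = 3))  # odd K: inputs never zero
    x0 <- random_initial_state(7, "pm1")
    expect_true(sigmoid_matches_sign(w, x0, a = 100, horizon = 100))
    # monotone sigma preserves an identity-fixed state for any steepness
    expect_true(sigmoid_matches_sign(diag(7), rep(1L, 7), a = 0.5))
  }
  expect_error(sigmoid_matches_sign(generate_matrix(ensemble_spec(6, k = 2)),
                                    random_initial_state(6, "pm1"), a = 100),
               "odd")
  expect_error(sigmoid_matches_sign(diag(3) * 2.5, rep(1L, 3), a = 1),
               "binary")
})

test_that("trajectory results serialize and trajectories export as TSV", {
  w <- -diag(2)
  res <- iterate_to_attractor(w, c(1L, 1L), dynamics_spec("pm1"),
                              keep_attractor = TRUE)
  js <- jsonlite::fromJSON(trajectory_to_json(res))
  expect_equal(js$outcome, "cycle")
  expect_equal(js$period, 2)
  traj <- simulate_trajectory(w, c(1L, 1L), dynamics_spec("pm1"), steps = 4)
  expect_equal(names(traj), c("time", "gene", "value"))
  expect_equal(nrow(traj), 10)
  expect_equal(traj$value[traj$gene == 1], c(1, -1, 1, -1, 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(traj, path)
  expect_equal(read.delim(path), traj)
})
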