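test_that("chip allocations normalize to influence-weight rows", {
  # a member who puts all 100 chips on self was uninfluenced: a_ii = 0
  row <- weights_from_chips(c(100, 0, 0), self_index = 1)
  expect_identical(row, c(1, 0, 0))
  expect_equal(1 - row[1], 0)

  expect_equal(weights_from_chips(c(0, 50, 50), self_index = 1), c(0, 0.5, 0.5))
  expect_equal(weights_from_chips(c(40, 40, 20)), c(0.4, 0.4, 0.2))

  # arithmetic slips (total != 100) renormalize by the row's own total
  expect_equal(weights_from_chips(c(40, 40, 25)), c(40, 40, 25) / 105)
  expect_equal(sum(weights_from_chips(c(3, 9, 1))), 1)

  expect_error(weights_from_chips(c(0, 0, 0)), class = "fjalloc_zero_chips")
  expect_error(weights_from_chips(c(-1, 50, 51)))
})

test_that("influence systems validate W and derive susceptibilities", {
  W <- rbind(c(0.6, 0.4), c(0.3, 0.7))
  sys <- influence_system(W)
  expect_equal(sys$A, 1 - diag(W))

  expect_error(influence_system(rbind(c(0.5, 0.4), c(0.3, 0.7))), "sums to")
  expect_error(influence_system(rbind(c(1.2, -0.2), c(0.3, 0.7))))
  expect_error(influence_from_chips(rbind(c(50, 50), c(0, 0))),
               class = "fjalloc_zero_chips")

  # chips with unequal totals still give a row-stochastic W
  sys2 <- influence_from_chips(rbind(c(60, 45), c(10, 90)))
  expect_equal(rowSums(sys2$W), c(1, 1))
})

test_that("one FJ step matches the scalar update in its limit cases", {
  W <- matrix(0.5, 2, 2)
  X0 <- matrix(c(0, 100), 2, 1)

  # A = 0: everyone restates the initial opinion, whatever X_k is
  anchored <- influence_system(diag(2))
  X_k <- matrix(c(42, 17), 2, 1)
  expect_identical(fj_step(X_k, anchored, X0), X0)

  # A = I: the DeGroot update W X_k
  dg <- degroot_system(W)
  expect_equal(fj_step(X_k, dg, X0), W %*% X_k)

  # hand-evaluated scalar FJ update: a = 0.5 each, one step from X(0)
  sys <- influence_system(W)
  expect_equal(fj_step(X0, sys, X0), matrix(c(25, 75), 2, 1))

  expect_error(fj_step(matrix(0, 3, 1), sys, X0), "n x m")
})

test_that("iteration converges under contraction and reports the limit", {
  X0 <- matrix(c(0, 100), 2, 1)

  # A = 0: converged at the first step with states[[2]] = X(0)
  traj0 <- fj_iterate(X0, influence_system(diag(2)))
  expect_true(traj0$converged)
  expect_equal(traj0$iterations, 1)
  expect_identical(traj0$states[[2]], X0)
  expect_identical(traj0$states[[1]], X0)

  # symmetric half-weights: limit is the hand-derived (25, 75)
  sys <- influence_system(matrix(0.5, 2, 2))
  traj <- fj_iterate(X0, sys, tol = 1e-12)
  expect_true(traj$converged)
  expect_equal(traj$final, matrix(c(25, 75), 2, 1), tolerance = 1e-10)
  expect_equal(length(traj$states), traj$iterations + 1)

  # any system with all a_ii < 1 contracts
  set.seed(11)
  for (i in 1:20) {
    n <- sample(2:5, 1)
    sys_i <- random_influence_system(n)
    traj_i <- fj_iterate(random_opinions(n, 3), sys_i, keep_states = FALSE)
    expect_true(traj_i$converged)
  }
})

test_that("total influence matrix matches hand inversion and is row-stochastic", {
  # A = 0 gives V = I
  expect_equal(total_influence(influence_system(diag(3))), diag(3))

  # 2x2 hand inversion: W = 1/2 everywhere, a = 1/2 -> V = [[.75,.25],[.25,.75]]
  sys <- influence_system(matrix(0.5, 2, 2))
  V <- total_influence(sys)
  expect_equal(V, rbind(c(0.75, 0.25), c(0.25, 0.75)), tolerance = 1e-12)

  # cross-check against iteration from unit initial opinions
  X0 <- diag(2) * 100
  traj <- fj_iterate(X0, sys, tol = 1e-14)
  expect_equal(V %*% X0, traj$final, tolerance = 1e-10)

  # row sums 1 and entries in [0, 1] on random systems
  set.seed(22)
  for (i in 1:200) {
    Vi <- total_influence(random_influence_system(sample(2:6, 1)))
    expect_lt(max(abs(rowSums(Vi) - 1)), 1e-9)
    expect_true(all(Vi >= -1e-12 & Vi <= 1 + 1e-12))
  }

  # periodic DeGroot system: I - AW singular, error points to iteration
  perm <- degroot_system(rbind(c(0, 1), c(1, 0)))
  expect_error(total_influence(perm), class = "fjalloc_singular_system")
})

test_that("equilibrium predictions follow X_hat = V X(0)", {
  X0 <- matrix(c(0, 100), 2, 1)
  sys <- influence_system(matrix(0.5, 2, 2))
  pred <- fj_equilibrium(X0, sys)
  expect_equal(pred$x_hat, matrix(c(25, 75), 2, 1), tolerance = 1e-12)
  expect_equal(pred$changes, matrix(c(25, -25), 2, 1), tolerance = 1e-12)
  expect_identical(pred$method, "closed_form")

  # A = 0: X_hat = X(0) exactly, zero changes
  pred0 <- fj_equilibrium(X0, influence_system(diag(2)))
  expect_identical(pred0$x_hat, X0)
  expect_true(all(pred0$changes == 0))

  # per-column computation agrees with the whole-matrix computation
  set.seed(33)
  sysr <- random_influence_system(4)
  X <- random_opinions(4, 3)
  whole <- fj_equilibrium(X, sysr)$x_hat
  by_col <- sapply(1:3, function(j) {
    fj_equilibrium(X[, j, drop = FALSE], sysr)$x_hat
  })
  expect_equal(whole, by_col, tolerance = 1e-12)

  # simplex rows stay on the simplex: convex combinations preserve row sums
  expect_equal(rowSums(whole), rowSums(X), tolerance = 1e-8)

  # tidy/glance accessors
  td <- tidy(pred)
  expect_equal(nrow(td), 2)
  expect_equal(td$predicted, c(25, 75), tolerance = 1e-12)
  expect_lt(glance(pred)$v_row_sum_dev, 1e-9)
})

test_that("closed form agrees with iteration on random systems", {
  set.seed(44)
  for (i in 1:150) {
    n <- sample(2:6, 1)
    m <- sample(2:4, 1)
    sys <- random_influence_system(n)
    X0 <- random_opinions(n, m)
    closed <- fj_equilibrium(X0, sys)
    traj <- fj_iterate(X0, sys, tol = 1e-12, keep_states = FALSE)
    expect_lt(max(abs(closed$x_hat - traj$final)), 1e-8)
  }
})

test_that("every equilibrium row stays in the convex hull of initial opinions", {
  set.seed(55)
  for (i in 1:50) {
    n <- sample(2:5, 1)
    sys <- random_influence_system(n)
    X0 <- random_opinions(n, 3)
    X_hat <- fj_equilibrium(X0, sys)$x_hat
    for (r in seq_len(n)) {
      expect_true(hull_contains(X0, X_hat[r, ], tol = 1e-7))
    }
  }
})

test_that("the DeGroot consensus certificate reads the network topology", {
  # W = I: no influence arcs between members, consensus not guaranteed
  cert_id <- degroot_consensus_certificate(diag(3))
  expect_false(cert_id$consensus_guaranteed)
  expect_true(is.na(cert_id$reachable_node))

  # complete uniform network with positive self-weights: guaranteed
  cert_cmp <- degroot_consensus_certificate(matrix(1 / 3, 3, 3))
  expect_true(cert_cmp$consensus_guaranteed)
  expect_equal(cert_cmp$reachable_node, 1L)
  expect_true(cert_cmp$aperiodic)

  # period-2 swap: globally reachable nodes exist but the w_ii > 0
  # certificate fails, and the DeGroot iteration indeed oscillates
  W_swap <- rbind(c(0, 1), c(1, 0))
  cert_swap <- degroot_consensus_certificate(W_swap)
  expect_true(is.na(cert_swap$consensus_guaranteed))
  expect_false(cert_swap$aperiodic)
  expect_false(is.na(cert_swap$reachable_node))
  traj <- fj_iterate(matrix(c(0, 100), 2, 1), degroot_system(W_swap),
                     max_iter = 101)
  expect_false(traj$converged)
  expect_equal(traj$final_residual, 100)

  # star listened to by everyone: hub reachable from all
  W_star <- rbind(c(1, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5))
  cert_star <- degroot_consensus_certificate(W_star)
  expect_true(cert_star$consensus_guaranteed)
  expect_equal(cert_star$reachable_node, 1L)
})
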