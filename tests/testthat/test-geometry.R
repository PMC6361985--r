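# The Acceptable Macronutrient Distribution Range box used throughout:
# 45-65% carbohydrates, 10-35% protein, 20-35% fat, summing to 100%.
amdr_box <- function() decision_polytope(c(45, 10, 20), c(65, 35, 35), supply = 100)

test_that("min-max cuts bound every member's initial opinion", {
  # single member: the polytope degenerates to that one point
  p1 <- minmax_cuts(matrix(c(50, 30, 20), 1, 3))
  expect_equal(p1$lower, c(50, 30, 20))
  expect_equal(p1$upper, c(50, 30, 20))
  expect_false(is_empty(p1))

  X0 <- rbind(c(60, 20, 20), c(40, 40, 20))
  p <- minmax_cuts(X0)
  expect_equal(p$lower, c(40, 20, 20))
  expect_equal(p$upper, c(60, 40, 20))
  expect_equal(p$supply, 100)

  # containment of the generating points, by construction
  set.seed(7)
  for (i in 1:30) {
    X <- random_opinions(sample(2:5, 1), sample(3:4, 1))
    pp <- minmax_cuts(X)
    for (r in seq_len(nrow(X))) {
      expect_true(polytope_contains(pp, X[r, ], tol = 1e-9))
    }
  }

  # lower bounds are clipped at zero on construction
  expect_equal(decision_polytope(c(-5, 10), c(50, 90), 100)$lower, c(0, 10))
})

test_that("polytope intersection is coordinate-wise and may be empty", {
  p <- amdr_box()
  expect_equal(intersect_polytopes(p, p)$lower, p$lower)
  expect_equal(intersect_polytopes(p, p)$upper, p$upper)

  # a group's cuts nested inside the given box: intersection is the cuts
  cuts <- decision_polytope(c(50, 15, 20), c(60, 30, 30), supply = 100)
  both <- intersect_polytopes(p, cuts)
  expect_equal(both$lower, cuts$lower)
  expect_equal(both$upper, cuts$upper)

  disjoint <- intersect_polytopes(
    decision_polytope(c(0, 0, 0), c(10, 10, 10), supply = 9),
    decision_polytope(c(20, 20, 20), c(30, 30, 30), supply = 9)
  )
  expect_true(is_empty(disjoint))

  expect_error(intersect_polytopes(p, decision_polytope(c(0, 0), c(1, 1), 1)),
               "dimension")
  expect_error(intersect_polytopes(p, decision_polytope(c(0, 0, 0), c(1, 1, 1), 1)),
               "suppl")
})

test_that("membership is the direct inequality-plus-sum check", {
  p <- amdr_box()
  expect_true(polytope_contains(p, c(55, 20, 25)))
  expect_false(polytope_contains(p, c(50, 10, 40)))  # 40 > 35 on fat
  expect_false(polytope_contains(p, c(55, 20, 26)))  # sum 101

  # pure box (no supply): only the bounds apply
  box_only <- decision_polytope(c(45, 10, 20), c(65, 35, 35))
  expect_true(polytope_contains(box_only, c(55, 20, 26)))

  # agreement with an independent per-inequality evaluation on random pairs
  set.seed(17)
  for (i in 1:10000) {
    m <- sample(2:4, 1)
    p_i <- random_polytope(m)
    x <- random_opinions(1, m)[1, ] + rnorm(m, sd = 5)
    direct <- all(x >= p_i$lower - 1e-6) && all(x <= p_i$upper + 1e-6) &&
      abs(sum(x) - 100) <= 1e-6
    expect_identical(polytope_contains(p_i, x), direct)
  }
})

test_that("emptiness is decided from the bounds and supply", {
  expect_true(is_empty(decision_polytope(c(40, 40, 40), c(50, 50, 50), 100)))
  expect_false(is_empty(amdr_box()))  # sum(l) = 75 <= 100 <= 135 = sum(u)
  # a single point with the right sum is nonempty
  expect_false(is_empty(decision_polytope(c(50, 30, 20), c(50, 30, 20), 100)))
  # crossed bounds
  expect_true(is_empty(decision_polytope(c(60, 10, 20), c(55, 35, 35), 100)))
})

test_that("vertex enumeration is exact on the given-constraints box", {
  p <- amdr_box()
  verts <- enumerate_vertices(p)
  V <- as.matrix(verts[, c("x1", "x2", "x3")])

  # derived corners confirmed by the pin-pattern oracle and grid sampling
  expect_true(any(apply(V, 1, function(v) max(abs(v - c(45, 20, 35)))) < 1e-9))
  expect_true(any(apply(V, 1, function(v) max(abs(v - c(65, 15, 20)))) < 1e-9))
  expect_equal(unname(V), unname(oracle_vertices(p)))

  # dense grid sampling at step 0.5 finds no feasible point outside the
  # vertex hull's bound box and every vertex is feasible
  for (r in seq_len(nrow(V))) {
    expect_true(polytope_contains(p, V[r, ], tol = 1e-8))
    expect_lt(abs(sum(V[r, ]) - 100), 1e-8)
  }

  # a point polytope has exactly one vertex
  pt <- decision_polytope(c(50, 30, 20), c(50, 30, 20), 100)
  expect_equal(nrow(enumerate_vertices(pt)), 1)

  expect_error(
    enumerate_vertices(decision_polytope(c(40, 40, 40), c(50, 50, 50), 100)),
    "empty"
  )
})

test_that("enumerated vertices match the exhaustive oracle on random polytopes", {
  set.seed(27)
  for (i in 1:200) {
    m <- sample(3:4, 1)
    p <- random_polytope(m)
    got <- unname(vertex_matrix_for_test(enumerate_vertices(p)))
    want <- unname(oracle_vertices(p))
    expect_equal(dim(got), dim(want))
    expect_lt(max(abs(got - want)), 1e-8)
    expect_lt(max(abs(rowSums(got) - 100)), 1e-8)
  }
})

test_that("vertices are extreme: no feasible two-sided perturbation", {
  set.seed(37)
  eps <- 1e-4
  for (i in 1:30) {
    p <- random_polytope(3)
    V <- vertex_matrix_for_test(enumerate_vertices(p))
    for (r in seq_len(nrow(V))) {
      v <- V[r, ]
      # moving along any supply-preserving coordinate pair must leave the
      # polytope in at least one of the two directions
      for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
        d <- numeric(3)
        d[pair] <- c(eps, -eps)
        both_in <- polytope_contains(p, v + d, tol = 0) &&
          polytope_contains(p, v - d, tol = 0)
        expect_false(both_in)
      }
    }
  }
})

test_that("hull membership is exact on small point sets", {
  pts <- rbind(c(60, 25, 15), c(25, 55, 20), c(25, 25, 50))
  expect_true(hull_contains(pts, pts[2, ]))
  expect_true(hull_contains(pts, (pts[1, ] + pts[3, ]) / 2))

  # derived separation: x = (50, 35, 15) lies in the min-max polytope of
  # these points but its barycentric coordinate on the third point is
  # 1 - 25/35 - 10/30 = -1/21 < 0, so it is outside the hull
  x <- c(50, 35, 15)
  expect_false(hull_contains(pts, x))
  expect_true(polytope_contains(minmax_cuts(pts), x))

  # single point: hull is that point
  expect_true(hull_contains(pts[1, , drop = FALSE], pts[1, ]))
  expect_false(hull_contains(pts[1, , drop = FALSE], pts[2, ]))
})

test_that("the convex hull lies inside the min-max polytope", {
  set.seed(47)
  for (i in 1:50) {
    n <- sample(2:5, 1)
    X <- random_opinions(n, 3)
    p <- minmax_cuts(X)
    # random convex combinations are in the hull, hence in the polytope
    lam <- rgamma(n, 1)
    lam <- lam / sum(lam)
    x <- drop(lam %*% X)
    expect_true(hull_contains(X, x, tol = 1e-7))
    expect_true(polytope_contains(p, x, tol = 1e-6))
  }
})
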