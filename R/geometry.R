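# Decision-space geometry: the allocation simplex sliced by a box of
# per-dimension bounds. Every decision space here is {l <= x <= u, sum(x) = s}
# (a box intersected with one hyperplane), so the H-representation is kept as
# bounds plus one optional equality and vertex enumeration stays exact.

#' Construct a box-on-simplex decision polytope
#'
#' Represents `{x : l <= x <= u, x >= 0, sum(x) = s}`, the decision space cut
#' from the allocation simplex by per-dimension lower and upper bounds. Lower
#' bounds are clipped at 0 on construction (allocations are non-negative).
#' With `supply = NA` the object is a plain box `{l <= x <= u}` with no sum
#' constraint, as needed for min/max constraint opinions that are not
#' themselves allocations.
#'
#' The constructor does not require `l <= u` or feasibility: intersections of
#' group decision spaces are legitimately empty, and [is_empty()] decides
#' feasibility (`sum(l) <= s <= sum(u)` and `l <= u` coordinate-wise).
#'
#' @param lower,upper Numeric m-vectors of per-dimension bounds, in
#'   allocation units.
#' @param supply The total to be allocated (`s > 0`), or `NA` for a pure box.
#' @return An object of class `decision_polytope` with fields `m`, `supply`,
#'   `lower`, `upper`.
#' @examples
#' decision_polytope(c(45, 10, 20), c(65, 35, 35), supply = 100)
#' @export
decision_polytope <- function(lower, upper, supply = NA_real_) {
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (length(lower) != length(upper) || length(lower) < 1) {
    abort("`lower` and `upper` must be numeric vectors of the same length.")
  }
  if (anyNA(lower) || anyNA(upper)) abort("bounds must not contain NA.")
  if (any(upper < 0)) abort("upper bounds must be non-negative.")
  supply <- as.numeric(supply)[1]
  if (!is.na(supply) && supply <= 0) abort("`supply` must be positive.")
  structure(
    list(m = length(lower), supply = supply, lower = pmax(lower, 0),
         upper = upper),
    class = "decision_polytope"
  )
}

#' @export
print.decision_polytope <- function(x, ...) {
  cat(sprintf(
    "<decision_polytope: %d dimensions, supply %s%s>\n",
    x$m,
    if (is.na(x$supply)) "unconstrained (box only)" else format(x$supply),
    if (is_empty(x)) ", EMPTY" else ""
  ))
  for (j in seq_len(x$m)) {
    cat(sprintf("  dim %d: [%g, %g]\n", j, x$lower[j], x$upper[j]))
  }
  invisible(x)
}

#' Implicit decision space cut by a group's extremal initial opinions
#'
#' A group deliberating over how to distribute a supply `s` among `m` options
#' implicitly defines a polytope of candidate distributions: on each
#' dimension, the coordinate-wise minimum and maximum of the members' initial
#' opinions cut the allocation simplex. Every member's initial opinion lies
#' in this polytope by construction, and weighted-averaging opinion dynamics
#' cannot leave it.
#'
#' @param X0 n x m matrix (or data frame) of initial opinions, one row per
#'   member.
#' @param supply The allocation total. Defaults to the common row sum of
#'   `X0`; pass `NA` for non-simplex opinion arrays (e.g. min/max constraint
#'   values), in which case the result is a pure box.
#' @return A [decision_polytope()].
#' @examples
#' X0 <- rbind(c(60, 20, 20), c(40, 40, 20))
#' minmax_cuts(X0)
#' @export
minmax_cuts <- function(X0, supply = NULL) {
  X0 <- as.matrix(X0)
  if (is.null(supply)) supply <- sum(X0[1, ])
  if (!is.na(supply)) {
    X0 <- check_opinions(X0, supply = supply, simplex = TRUE, tol = 1e-6,
                         arg = "X0")
  }
  decision_polytope(
    lower = apply(X0, 2, min),
    upper = apply(X0, 2, max),
    supply = supply
  )
}

#' Intersect two decision polytopes
#'
#' Coordinate-wise: the lower bounds are the maxima of the two lower bounds,
#' the upper bounds the minima of the two uppers. Used when an experiment
#' imposes explicit bounds on top of the group's implicit min-max cuts (the
#' implicit polytope may then be a subspace of the given decision space).
#' The result may be empty.
#'
#' @param p1,p2 [decision_polytope()] objects with the same dimension count
#'   and supply.
#' @return A [decision_polytope()].
#' @examples
#' amdr <- decision_polytope(c(45, 10, 20), c(65, 35, 35), supply = 100)
#' cuts <- decision_polytope(c(50, 15, 20), c(60, 30, 30), supply = 100)
#' intersect_polytopes(amdr, cuts)
#' @export
intersect_polytopes <- function(p1, p2) {
  stopifnot(inherits(p1, "decision_polytope"), inherits(p2, "decision_polytope"))
  if (p1$m != p2$m) abort("polytopes have different dimension counts.")
  same_supply <- (is.na(p1$supply) && is.na(p2$supply)) ||
    (!is.na(p1$supply) && !is.na(p2$supply) &&
       isTRUE(all.equal(p1$supply, p2$supply)))
  if (!same_supply) abort("polytopes have different supplies.")
  decision_polytope(
    lower = pmax(p1$lower, p2$lower),
    upper = pmin(p1$upper, p2$upper),
    supply = p1$supply
  )
}

#' Test whether a point lies in a decision polytope
#'
#' True iff `l_j - tol <= x_j <= u_j + tol` on every dimension and, when the
#' polytope carries a supply, `|sum(x) - s| <= tol`. The default tolerance is
#' deliberately loose relative to machine precision because recorded
#' positions are integers in allocation units (percent): it decides whether
#' a recorded final position counts as located on the decision space.
#'
#' @param p A [decision_polytope()].
#' @param x Numeric m-vector.
#' @param tol Membership tolerance in allocation units.
#' @return Logical flag.
#' @examples
#' amdr <- decision_polytope(c(45, 10, 20), c(65, 35, 35), supply = 100)
#' polytope_contains(amdr, c(55, 20, 25))
#' polytope_contains(amdr, c(50, 10, 40))
#' @export
polytope_contains <- function(p, x, tol = 1e-6) {
  stopifnot(inherits(p, "decision_polytope"))
  x <- as.numeric(x)
  if (length(x) != p$m) abort("`x` must have one entry per dimension.")
  all(x >= p$lower - tol) && all(x <= p$upper + tol) &&
    (is.na(p$supply) || abs(sum(x) - p$supply) <= tol)
}

#' Is a decision polytope empty?
#'
#' Feasibility is decidable from the bounds alone: the polytope is nonempty
#' iff `l_j <= u_j` on every dimension and (when a supply is present)
#' `sum(l) <= s <= sum(u)`.
#'
#' @param p A [decision_polytope()].
#' @param tol Numerical slack on the comparisons.
#' @return Logical flag.
#' @examples
#' is_empty(decision_polytope(c(40, 40, 40), c(50, 50, 50), supply = 100))
#' @export
is_empty <- function(p, tol = 1e-9) {
  stopifnot(inherits(p, "decision_polytope"))
  if (any(p$lower > p$upper + tol)) return(TRUE)
  if (!is.na(p$supply)) {
    if (sum(p$lower) > p$supply + tol) return(TRUE)
    if (sum(p$upper) < p$supply - tol) return(TRUE)
  }
  FALSE
}

#' Enumerate the vertices of a box-on-simplex polytope
#'
#' At a vertex of `{l <= x <= u, sum(x) = s}`, m - 1 coordinates are pinned
#' at a lower or upper bound and the remaining coordinate is determined by
#' the supply equality. The enumeration tries every choice of free
#' coordinate and every lower/upper pin pattern on the others (`m * 2^(m-1)`
#' candidates), keeps the feasible ones, and deduplicates coincident corners
#' in max-norm. Exact for the dimension counts that arise in allocation
#' tasks (intended for m <= 6).
#'
#' @param p A nonempty [decision_polytope()] with a finite supply.
#' @param feas_tol Feasibility slack on the free coordinate.
#' @param dedup_tol Max-norm radius within which candidate vertices are
#'   considered the same corner.
#' @return A tibble with columns `vertex` (index) and `x1` ... `xm`, sorted
#'   lexicographically.
#' @examples
#' amdr <- decision_polytope(c(45, 10, 20), c(65, 35, 35), supply = 100)
#' enumerate_vertices(amdr)
#' @export
enumerate_vertices <- function(p, feas_tol = 1e-8, dedup_tol = 1e-8) {
  stopifnot(inherits(p, "decision_polytope"))
  if (is.na(p$supply)) {
    abort("vertex enumeration requires the supply equality constraint.")
  }
  if (is_empty(p)) abort("cannot enumerate the vertices of an empty polytope.")
  m <- p$m
  cands <- list()
  if (m == 1) {
    cands[[1]] <- p$supply
  } else {
    pin_patterns <- as.matrix(expand.grid(
      rep(list(c(FALSE, TRUE)), m - 1), KEEP.OUT.ATTRS = FALSE
    ))
    for (free in seq_len(m)) {
      others <- setdiff(seq_len(m), free)
      for (r in seq_len(nrow(pin_patterns))) {
        at_upper <- pin_patterns[r, ]
        x <- numeric(m)
        x[others] <- ifelse(at_upper, p$upper[others], p$lower[others])
        x[free] <- p$supply - sum(x[others])
        if (x[free] >= p$lower[free] - feas_tol &&
            x[free] <= p$upper[free] + feas_tol) {
          cands[[length(cands) + 1L]] <- x
        }
      }
    }
  }
  V <- do.call(rbind, cands)
  keep <- rep(TRUE, nrow(V))
  for (i in seq_len(nrow(V))) {
    if (!keep[i]) next
    if (i < nrow(V)) {
      later <- (i + 1L):nrow(V)
      dup <- later[apply(
        abs(V[later, , drop = FALSE] -
              matrix(V[i, ], length(later), m, byrow = TRUE)),
        1, max
      ) <= dedup_tol]
      keep[dup] <- FALSE
    }
  }
  V <- V[keep, , drop = FALSE]
  V <- V[do.call(order, as.data.frame(V)), , drop = FALSE]
  out <- tibble::as_tibble(as.data.frame(V), .name_repair = "minimal")
  names(out) <- paste0("x", seq_len(m))
  tibble::add_column(out, vertex = seq_len(nrow(out)), .before = 1)
}

vertex_matrix <- function(vertices) {
  as.matrix(vertices[, setdiff(names(vertices), "vertex"), drop = FALSE])
}

#' Convex-hull membership for small point sets
#'
#' Decides whether `x` is a convex combination of the given points: whether
#' there are weights `lambda >= 0`, `sum(lambda) = 1`, with
#' `x = sum(lambda_i p_i)`. Solved exactly for group-sized instances via
#' Caratheodory's theorem: if `x` lies in the hull it is a convex combination
#' of some affinely independent subset of at most m + 1 points, so every such
#' subset is tested by solving its (full-column-rank) barycentric system.
#'
#' The hull of a group's initial opinions is contained in -- and generally
#' strictly smaller than -- the min-max polytope those opinions cut
#' ([minmax_cuts()]): weighted averaging confines settled opinions to the
#' hull, hence to the decision space.
#'
#' @param points Matrix or data frame with one point per row (intended for
#'   at most 8-12 points, i.e. group-sized instances).
#' @param x Numeric vector, one entry per column of `points`.
#' @param tol Tolerance on the barycentric weights and residual.
#' @return Logical flag.
#' @examples
#' pts <- rbind(c(60, 20, 20), c(20, 60, 20), c(20, 20, 60))
#' hull_contains(pts, colMeans(pts))
#' hull_contains(pts, c(60, 60, -20))
#' @export
hull_contains <- function(points, x, tol = 1e-8) {
  P <- as.matrix(points)
  x <- as.numeric(x)
  if (ncol(P) != length(x)) abort("`x` must match the point dimension.")
  k <- nrow(P)
  if (k < 1) abort("`points` must contain at least one point.")
  if (k > 12) {
    abort("hull membership is implemented for small point sets (<= 12 points).")
  }
  m <- ncol(P)
  scale <- max(1, abs(P), abs(x))
  target <- c(x, 1)
  for (size in seq_len(min(k, m + 1))) {
    subsets <- combn(k, size)
    for (s in seq_len(ncol(subsets))) {
      idx <- subsets[, s]
      A <- rbind(t(P[idx, , drop = FALSE]), rep(1, size))
      qrA <- qr(A)
      if (qrA$rank < size) next
      lam <- qr.coef(qrA, target)
      if (anyNA(lam)) next
      if (min(lam) >= -tol &&
          max(abs(A %*% lam - target)) <= tol * scale) {
        return(TRUE)
      }
    }
  }
  FALSE
}
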