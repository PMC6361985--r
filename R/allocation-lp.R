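# Linear programs over a box-on-simplex decision polytope, solved by exact
# vertex enumeration: the feasible set is a bounded polytope, so an optimum
# lies at a vertex and scoring every vertex is both exact and cheap at the
# dimension counts of allocation tasks.

#' Define a linear program over a decision polytope
#'
#' The optimisation variant of the allocation task: maximise a linear
#' payoff `c . x` (e.g. device performance per unit allocated to each work
#' category) over the feasible distributions `{l <= x <= u, sum(x) = s}`.
#'
#' @param objective Numeric m-vector of objective coefficients, in payoff
#'   units per allocation unit.
#' @param polytope A [decision_polytope()] with a finite supply.
#' @return An object of class `allocation_lp`.
#' @examples
#' p <- decision_polytope(c(0.45, 0.10, 0.20), c(0.65, 0.35, 0.35), supply = 1)
#' allocation_lp(c(1.25, 1.50, 1.75), p)
#' @export
allocation_lp <- function(objective, polytope) {
  stopifnot(inherits(polytope, "decision_polytope"))
  objective <- as.numeric(objective)
  if (length(objective) != polytope$m || anyNA(objective)) {
    abort("`objective` must be a numeric vector with one coefficient per dimension.")
  }
  if (is.na(polytope$supply)) {
    abort("the LP requires a polytope with a supply equality.")
  }
  structure(list(objective = objective, polytope = polytope),
            class = "allocation_lp")
}

#' @export
print.allocation_lp <- function(x, ...) {
  cat(sprintf(
    "<allocation_lp: maximise (%s) . x over %d-dim polytope, supply %g>\n",
    paste(format(x$objective), collapse = ", "), x$polytope$m,
    x$polytope$supply
  ))
  invisible(x)
}

#' Solve an allocation linear program by vertex enumeration
#'
#' Scores every vertex of the feasible polytope against the objective and
#' returns the maximiser. All vertices within a relative tie tolerance of
#' the best value are reported as alternative optima (a constant objective
#' makes every vertex optimal); `x_star` is the lexicographically smallest
#' optimal vertex, a deterministic tie-break.
#'
#' @param problem An [allocation_lp()].
#' @param tie_tol Relative tolerance within which vertices count as
#'   alternative optima.
#' @return An object of class `allocation_solution`: list with `x_star`
#'   (optimal allocation), `objective` (its payoff `c . x_star`), and
#'   `all_optima` (tibble of tying vertices with their values).
#' @examples
#' p <- decision_polytope(c(0.45, 0.10, 0.20), c(0.65, 0.35, 0.35), supply = 1)
#' solve_allocation_lp(allocation_lp(c(1.25, 1.50, 1.75), p))
#' @export
solve_allocation_lp <- function(problem, tie_tol = 1e-9) {
  stopifnot(inherits(problem, "allocation_lp"))
  if (is_empty(problem$polytope)) {
    abort("the feasible polytope is empty: the problem is infeasible.",
          class = "fjalloc_infeasible")
  }
  verts <- enumerate_vertices(problem$polytope)
  V <- vertex_matrix(verts)
  scores <- drop(V %*% problem$objective)
  best <- max(scores)
  tie <- scores >= best - tie_tol * max(1, abs(best))
  optima <- V[tie, , drop = FALSE]
  optima <- optima[do.call(order, as.data.frame(optima)), , drop = FALSE]
  x_star <- optima[1, ]
  all_optima <- tibble::as_tibble(as.data.frame(optima), .name_repair = "minimal")
  names(all_optima) <- paste0("x", seq_len(ncol(optima)))
  all_optima$value <- drop(optima %*% problem$objective)
  structure(
    list(
      x_star = unname(x_star),
      objective = sum(problem$objective * x_star),
      all_optima = all_optima
    ),
    class = "allocation_solution"
  )
}

#' @export
print.allocation_solution <- function(x, ...) {
  cat(sprintf(
    "<allocation_solution: x* = (%s), objective %g%s>\n",
    paste(format(x$x_star), collapse = ", "), x$objective,
    if (nrow(x$all_optima) > 1) {
      sprintf(" (%d tying vertices)", nrow(x$all_optima))
    } else {
      ""
    }
  ))
  invisible(x)
}

#' Grade a proposed allocation against the LP optimum
#'
#' Classifies a subject's answer to the optimisation task: feasibility is
#' membership in the decision polytope, optimality is a payoff within `tol`
#' of the solved optimum, and `gap` is how much payoff the answer leaves on
#' the table (optimum minus achieved; reported for infeasible answers too).
#' Subject answers are typically two-decimal fractions, so the default
#' optimality tolerance is generous but safe.
#'
#' @param problem An [allocation_lp()].
#' @param x Numeric m-vector, the proposed allocation.
#' @param tol Optimality tolerance in objective (payoff) units.
#' @param feas_tol Membership tolerance passed to [polytope_contains()].
#' @return A one-row tibble with columns `feasible`, `optimal`, `value`,
#'   `gap`.
#' @examples
#' p <- decision_polytope(c(0.45, 0.10, 0.20), c(0.65, 0.35, 0.35), supply = 1)
#' lp <- allocation_lp(c(1.25, 1.50, 1.75), p)
#' grade_solution(lp, c(0.65, 0.15, 0.20))
#' @export
grade_solution <- function(problem, x, tol = 1e-6, feas_tol = 1e-6) {
  stopifnot(inherits(problem, "allocation_lp"))
  x <- as.numeric(x)
  if (length(x) != problem$polytope$m) {
    abort("`x` must have one entry per dimension.")
  }
  sol <- solve_allocation_lp(problem)
  feasible <- polytope_contains(problem$polytope, x, tol = feas_tol)
  value <- sum(problem$objective * x)
  gap <- sol$objective - value
  tibble::tibble(
    feasible = feasible,
    optimal = feasible && gap <= tol,
    value = value,
    gap = gap
  )
}
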