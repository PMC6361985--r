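# Friedkin-Johnsen / DeGroot opinion dynamics on n x m opinion arrays.
#
# Opinions are n x m numeric matrices: one row per group member, one column
# per allocation dimension. The influence system couples a row-stochastic
# weight matrix W with the susceptibility vector a_ii = 1 - w_ii.

#' Construct an influence system from a weight matrix
#'
#' Bundles a row-stochastic influence matrix `W` with the susceptibility
#' vector it implies. Member `i`'s susceptibility to interpersonal influence
#' is `a_ii = 1 - w_ii`: a member who keeps all weight on self (`w_ii = 1`)
#' is anchored to their initial opinion and the conversation moves them not
#' at all; a member with `w_ii = 0` is fully open to influence.
#'
#' @param W Square numeric matrix of influence weights. Every entry must lie
#'   in `[0, 1]` and every row must sum to 1 (within `tol`). Row `i` is member
#'   `i`'s distribution of weight over all members, self included.
#' @param tol Validation tolerance on entries and row sums.
#'
#' @return An object of class `influence_system`: a list with elements `W`
#'   (the weight matrix), `A` (the susceptibility vector `1 - diag(W)`), and
#'   `n` (the group size).
#'
#' @examples
#' influence_system(matrix(c(0.6, 0.4, 0.3, 0.7), 2, byrow = TRUE))
#' @export
influence_system <- function(W, tol = 1e-9) {
  W <- as.matrix(W)
  if (!is.numeric(W) || nrow(W) != ncol(W) || nrow(W) < 1) {
    abort("`W` must be a square numeric matrix.")
  }
  if (anyNA(W)) abort("`W` must not contain missing values.")
  if (any(W < -tol) || any(W > 1 + tol)) {
    abort("all influence weights must lie in [0, 1].")
  }
  rs <- rowSums(W)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad) > 0) {
    abort(sprintf(
      "row %d of `W` sums to %.6g; every row must sum to 1 (tolerance %g).",
      bad[1], rs[bad[1]], tol
    ))
  }
  structure(
    list(W = unname(W), A = unname(1 - diag(W)), n = nrow(W)),
    class = "influence_system"
  )
}

#' @export
print.influence_system <- function(x, ...) {
  cat(sprintf("<influence_system: %d members>\n", x$n))
  cat("W:\n")
  print(round(x$W, 4))
  cat("susceptibilities a_ii = 1 - w_ii:", paste(round(x$A, 4), collapse = " "), "\n")
  invisible(x)
}

#' The DeGroot special case: pure iterative weighted averaging
#'
#' Constructs the influence system of the DeGroot model, in which every
#' member is fully susceptible (`A = I`) and opinions evolve by
#' `X(k+1) = W X(k)` with no anchorage to initial opinions. This is the
#' limiting special case of the Friedkin-Johnsen dynamics; note that a
#' measured chip-based system always derives `a_ii = 1 - w_ii` instead
#' ([influence_system()]), so `A = I` there would require `w_ii = 0` for
#' all members.
#'
#' The closed-form equilibrium never applies to a DeGroot system (`I - W`
#' is singular because `W` is row-stochastic); [fj_equilibrium()] takes the
#' iterative path, which converges exactly when the network guarantees
#' consensus or the initial opinions already agree along periodic orbits
#' (see [degroot_consensus_certificate()]).
#'
#' @param W Row-stochastic weight matrix.
#' @param tol Validation tolerance.
#' @return An `influence_system` with all susceptibilities equal to 1.
#' @examples
#' degroot_system(matrix(1 / 3, 3, 3))
#' @export
degroot_system <- function(W, tol = 1e-9) {
  sys <- influence_system(W, tol = tol)
  sys$A <- rep(1, sys$n)
  sys
}

#' Convert one member's chip allocation into a row of influence weights
#'
#' Group members report influence by distributing 100 chips over the members
#' of their group (themselves included); chips placed on self measure how far
#' the final answer was unaffected by the conversation. The reported counts
#' are a relative weight distribution, so rows are normalized by their own
#' total: totals that miss 100 through arithmetic slips are accepted, a total
#' of zero is an unusable self-report and is rejected.
#'
#' @param chips Non-negative numeric vector of chip counts, one entry per
#'   group member in member order.
#' @param self_index Optional position of the reporting member; only used to
#'   validate that it indexes `chips`.
#'
#' @return Numeric vector of the same length summing to 1: one row of `W`.
#'
#' @examples
#' weights_from_chips(c(100, 0, 0))  # conversation had no influence
#' weights_from_chips(c(40, 40, 20))
#' @export
weights_from_chips <- function(chips, self_index = NULL) {
  chips <- as.numeric(chips)
  if (anyNA(chips) || any(chips < 0)) {
    abort("`chips` must be non-negative counts.")
  }
  if (!is.null(self_index) &&
      (self_index < 1 || self_index > length(chips))) {
    abort("`self_index` must index into `chips`.")
  }
  total <- sum(chips)
  if (total <= 0) {
    abort("all-zero chip allocation: unusable self-report.",
          class = "fjalloc_zero_chips")
  }
  chips / total
}

#' Build an influence system from a group's chip matrix
#'
#' @param chips n x n matrix whose row `i` is member `i`'s chip allocation
#'   over the group.
#' @param tol Row-sum validation tolerance passed to [influence_system()].
#' @return An [influence_system()] object.
#' @examples
#' influence_from_chips(rbind(c(60, 20, 20), c(10, 80, 10), c(25, 25, 50)))
#' @export
influence_from_chips <- function(chips, tol = 1e-9) {
  chips <- as.matrix(chips)
  if (nrow(chips) != ncol(chips)) {
    abort("`chips` must be square: one row per member, one column per member.")
  }
  W <- t(vapply(
    seq_len(nrow(chips)),
    function(i) weights_from_chips(chips[i, ], self_index = i),
    numeric(ncol(chips))
  ))
  influence_system(W, tol = tol)
}

check_opinions <- function(X, supply = NULL, simplex = TRUE, tol = 1e-9,
                           arg = "X") {
  X <- as.matrix(X)
  if (!is.numeric(X) || anyNA(X)) {
    abort(sprintf("`%s` must be a numeric matrix without missing values.", arg))
  }
  if (isTRUE(simplex)) {
    if (any(X < -tol)) {
      abort(sprintf("`%s` has negative entries; allocations must be >= 0.", arg))
    }
    rs <- rowSums(X)
    if (is.null(supply)) supply <- rs[1]
    bad <- which(abs(rs - supply) > tol)
    if (length(bad) > 0) {
      abort(sprintf(
        "row %d of `%s` sums to %.6g, not the supply %.6g.",
        bad[1], arg, rs[bad[1]], supply
      ))
    }
  }
  unname(X)
}

#' One Friedkin-Johnsen update of a group opinion array
#'
#' Applies `X(k+1) = A W X(k) + (I - A) X(0)`: each member forms a weighted
#' average of the group's displayed opinions, blended with an ongoing
#' attachment to their own initial opinion in proportion `1 - a_ii`. With
#' `A = I` (no anchorage) this is the DeGroot update `W X(k)`; with `A = 0`
#' every member restates their initial opinion.
#'
#' @param X_k Current n x m opinion matrix.
#' @param system An [influence_system()].
#' @param X0 The fixed n x m matrix of initial opinions.
#' @return The updated n x m opinion matrix.
#' @examples
#' sys <- influence_system(matrix(0.5, 2, 2))
#' fj_step(matrix(c(0, 100), 2, 1), sys, matrix(c(0, 100), 2, 1))
#' @export
fj_step <- function(X_k, system, X0) {
  stopifnot(inherits(system, "influence_system"))
  X_k <- as.matrix(X_k)
  X0 <- as.matrix(X0)
  if (nrow(X_k) != system$n || !all(dim(X_k) == dim(X0))) {
    abort("opinion arrays must be n x m with n matching the influence system.")
  }
  system$A * (system$W %*% X_k) + (1 - system$A) * X0
}

#' Iterate the Friedkin-Johnsen dynamics to (approximate) equilibrium
#'
#' Repeatedly applies [fj_step()] from `X0` until the largest absolute
#' one-step change falls below `tol` or `max_iter` steps have been taken.
#' Non-convergence is reported in the result, not raised: a periodic DeGroot
#' system (e.g. two members who each put all weight on the other) genuinely
#' oscillates, and the trajectory is the honest description of it.
#'
#' @param X0 Initial n x m opinion matrix.
#' @param system An [influence_system()].
#' @param max_iter Maximum number of update steps.
#' @param tol Convergence threshold on the max-norm one-step change.
#' @param keep_states If `TRUE` (default), record every intermediate state.
#'
#' @return An object of class `fj_trajectory`: list with `states` (list of
#'   opinion matrices, `states[[1]]` being `X0`), `converged`, `iterations`
#'   (number of steps taken, `length(states) - 1`), and `final_residual`.
#'
#' @examples
#' sys <- influence_system(matrix(0.5, 2, 2))
#' traj <- fj_iterate(matrix(c(0, 100), 2, 1), sys)
#' traj$converged
#' @export
fj_iterate <- function(X0, system, max_iter = 1e5, tol = 1e-10,
                       keep_states = TRUE) {
  stopifnot(inherits(system, "influence_system"), max_iter >= 1, tol > 0)
  X0 <- as.matrix(X0)
  X <- X0
  states <- if (keep_states) list(X0) else list()
  converged <- FALSE
  resid <- Inf
  k <- 0L
  while (k < max_iter) {
    X_next <- fj_step(X, system, X0)
    resid <- max(abs(X_next - X))
    k <- k + 1L
    X <- X_next
    if (keep_states) states[[k + 1L]] <- X
    if (resid < tol) {
      converged <- TRUE
      break
    }
  }
  if (!keep_states) states <- list(X0, X)
  structure(
    list(
      states = states, converged = converged, iterations = k,
      final_residual = resid, final = X
    ),
    class = "fj_trajectory"
  )
}

#' @export
print.fj_trajectory <- function(x, ...) {
  cat(sprintf(
    "<fj_trajectory: %d iterations, %s, final residual %.3g>\n",
    x$iterations, if (x$converged) "converged" else "not converged",
    x$final_residual
  ))
  invisible(x)
}

#' Total influence matrix of a Friedkin-Johnsen system
#'
#' Computes `V = (I - AW)^{-1} (I - A)`, the row-stochastic matrix that maps
#' the group's initial opinions to its equilibrium opinions (`X_hat = V X(0)`).
#' Entry `v_ij` is the total -- direct plus indirect, through the network --
#' influence of member `j`'s initial opinion on member `i`'s settled opinion.
#'
#' `I - AW` is singular when every member is fully susceptible (`A = I`,
#' since `W` is row-stochastic) and near-singular in related degenerate
#' configurations; those cases raise an error directing the caller to the
#' iterative path ([fj_iterate()]), which still characterises the dynamics.
#'
#' @param system An [influence_system()].
#' @param rcond_min Reciprocal-condition threshold below which `I - AW` is
#'   treated as singular.
#' @return The n x n total influence matrix `V`.
#' @examples
#' sys <- influence_from_chips(rbind(c(50, 50), c(50, 50)))
#' total_influence(sys)
#' @export
total_influence <- function(system, rcond_min = 1e-12) {
  stopifnot(inherits(system, "influence_system"))
  n <- system$n
  M <- diag(n) - system$A * system$W
  rc <- rcond(M)
  if (!is.finite(rc) || rc < rcond_min) {
    abort(
      paste(
        "I - AW is singular or near-singular (reciprocal condition",
        sprintf("%.3g); use the iterative path `fj_iterate()`.", rc)
      ),
      class = "fjalloc_singular_system"
    )
  }
  V <- solve(M, diag(1 - system$A, n))
  unname(V)
}

#' Equilibrium opinions predicted by the Friedkin-Johnsen model
#'
#' Predicts the group's settled opinions `X_hat = V X(0)` by the closed form
#' when `I - AW` is well conditioned, falling back to fixed-point iteration
#' otherwise (the singularity error propagates only if iteration also fails
#' to converge). The predicted net opinion changes are `X_hat - X(0)`.
#'
#' Because every row of `V` is a set of convex-combination weights, each
#' member's predicted opinion is a convex combination of the group's initial
#' opinions: row sums (the allocation supply) are preserved and no prediction
#' leaves the convex hull of the initial opinion array.
#'
#' @param X0 Initial n x m opinion matrix.
#' @param system An [influence_system()].
#' @param max_iter,tol Iteration controls for the fallback path.
#' @return An object of class `fj_prediction`: list with `x_hat`, `v` (the
#'   total influence matrix, `NULL` on the iterative path), `changes`
#'   (`x_hat - X0`), `method` (`"closed_form"` or `"iterative"`), `x0`, and
#'   `converged`.
#' @examples
#' sys <- influence_from_chips(rbind(c(50, 50), c(50, 50)))
#' fj_equilibrium(matrix(c(0, 100), 2, 1), sys)
#' @export
fj_equilibrium <- function(X0, system, max_iter = 1e5, tol = 1e-10) {
  stopifnot(inherits(system, "influence_system"))
  X0 <- as.matrix(X0)
  if (nrow(X0) != system$n) {
    abort("`X0` must have one row per member of the influence system.")
  }
  V <- tryCatch(total_influence(system), fjalloc_singular_system = function(e) NULL)
  if (!is.null(V)) {
    X_hat <- V %*% X0
    method <- "closed_form"
    converged <- TRUE
  } else {
    traj <- fj_iterate(X0, system, max_iter = max_iter, tol = tol,
                       keep_states = FALSE)
    if (!traj$converged) {
      abort(
        paste(
          "closed form unavailable (I - AW singular) and iteration did not",
          sprintf("converge within %d steps (residual %.3g).",
                  traj$iterations, traj$final_residual)
        ),
        class = "fjalloc_singular_system"
      )
    }
    X_hat <- traj$final
    method <- "iterative"
    converged <- TRUE
  }
  structure(
    list(
      x_hat = unname(X_hat), v = V, changes = unname(X_hat - X0),
      method = method, x0 = unname(X0), converged = converged
    ),
    class = "fj_prediction"
  )
}

#' @export
print.fj_prediction <- function(x, ...) {
  cat(sprintf(
    "<fj_prediction: %d members x %d dimensions, %s>\n",
    nrow(x$x_hat), ncol(x$x_hat), x$method
  ))
  cat("predicted equilibrium opinions:\n")
  print(round(x$x_hat, 4))
  invisible(x)
}

#' @describeIn fj_equilibrium Tidy a prediction into one row per member and
#'   dimension with initial, predicted, and change values.
#' @param x An `fj_prediction` object.
#' @param ... Unused.
#' @export
tidy.fj_prediction <- function(x, ...) {
  n <- nrow(x$x_hat)
  m <- ncol(x$x_hat)
  tibble::tibble(
    member = rep(seq_len(n), times = m),
    dimension = rep(seq_len(m), each = n),
    initial = as.vector(x$x0),
    predicted = as.vector(x$x_hat),
    change = as.vector(x$changes)
  )
}

#' @describeIn fj_equilibrium One-row summary: method, sizes, largest
#'   predicted change, and the worst deviation of a row of `V` from summing
#'   to 1 (`NA` on the iterative path).
#' @export
glance.fj_prediction <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_members = nrow(x$x_hat),
    n_dimensions = ncol(x$x_hat),
    max_abs_change = max(abs(x$changes)),
    v_row_sum_dev = if (is.null(x$v)) NA_real_ else max(abs(rowSums(x$v) - 1))
  )
}

#' Certify DeGroot consensus from the influence network topology
#'
#' Under pure iterative weighted averaging (the DeGroot model, `A = I`),
#' consensus is guaranteed when the influence network has at least one
#' globally reachable node -- a member whose opinion influences, directly or
#' indirectly, every other member -- together with an aperiodicity condition,
#' of which `w_ii > 0` for all `i` is the standard sufficient case. The arc
#' `i -> j` exists when `w_ij > 0` (member `i` weights member `j`), so a
#' globally reachable node is one reachable from every member along arcs.
#'
#' Only the sufficient self-weight condition is certified: a network with a
#' globally reachable node but some zero self-weights may still reach
#' consensus (aperiodicity can hold through cycles), so such cases are
#' labelled undetermined (`consensus_guaranteed = NA`) rather than decided.
#'
#' @param W Row-stochastic weight matrix.
#' @param tol Validation tolerance on `W`.
#' @return A list with `consensus_guaranteed` (`TRUE`, `FALSE` when no node
#'   is globally reachable, `NA` when undetermined), `reachable_node` (the
#'   smallest globally reachable member index, or `NA`), and `aperiodic`
#'   (whether the `w_ii > 0` certificate holds).
#' @examples
#' degroot_consensus_certificate(matrix(1 / 3, 3, 3))
#' degroot_consensus_certificate(diag(3))
#' @export
degroot_consensus_certificate <- function(W, tol = 1e-9) {
  sys <- influence_system(W, tol = tol)  # validates row-stochasticity
  W <- sys$W
  g <- igraph::graph_from_adjacency_matrix(
    (W > 0) * 1, mode = "directed", diag = TRUE
  )
  d <- igraph::distances(g, mode = "out")
  globally_reachable <- which(apply(is.finite(d), 2, all))
  aperiodic <- all(diag(W) > 0)
  if (length(globally_reachable) == 0) {
    guaranteed <- FALSE
  } else if (aperiodic) {
    guaranteed <- TRUE
  } else {
    guaranteed <- NA
  }
  list(
    consensus_guaranteed = guaranteed,
    reachable_node = if (length(globally_reachable) > 0) {
      as.integer(min(globally_reachable))
    } else {
      NA_integer_
    },
    aperiodic = aperiodic
  )
}
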