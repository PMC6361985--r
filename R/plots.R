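# ggplot2 views of the result types: the simplex-plane decision space for
# three-dimensional allocation issues, observed-versus-predicted agreement,
# and the noise-recovery curve.

# project points on the s-simplex (m = 3) onto the plane of the triangle
ternary_xy <- function(X, supply) {
  X <- as.matrix(X) / supply
  tibble::tibble(
    px = X[, 2] + 0.5 * X[, 3],
    py = sqrt(3) / 2 * X[, 3]
  )
}

#' Plot a three-dimensional decision polytope on the allocation simplex
#'
#' Draws the triangular plane of all distributions of the supply over three
#' options, the polytope cut on it by the min-max bounds (its vertices
#' joined in hull order), and optionally a set of opinion points (e.g. a
#' group's initial and final positions).
#'
#' @param object A nonempty [decision_polytope()] with `m = 3` and a finite
#'   supply.
#' @param points Optional matrix/data frame of opinion rows to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' amdr <- decision_polytope(c(45, 10, 20), c(65, 35, 35), supply = 100)
#' autoplot(amdr)
#' @export
autoplot.decision_polytope <- function(object, points = NULL, ...) {
  if (object$m != 3 || is.na(object$supply)) {
    abort("plotting is implemented for 3-dimensional simplex polytopes.")
  }
  s <- object$supply
  tri <- ternary_xy(rbind(c(s, 0, 0), c(0, s, 0), c(0, 0, s)), s)
  verts <- vertex_matrix(enumerate_vertices(object))
  vxy <- ternary_xy(verts, s)
  ctr <- c(mean(vxy$px), mean(vxy$py))
  vxy <- vxy[order(atan2(vxy$py - ctr[2], vxy$px - ctr[1])), ]
  p <- ggplot2::ggplot() +
    ggplot2::geom_polygon(
      data = tri, ggplot2::aes(x = .data$px, y = .data$py),
      fill = "steelblue", alpha = 0.15, colour = "steelblue"
    ) +
    ggplot2::geom_polygon(
      data = vxy, ggplot2::aes(x = .data$px, y = .data$py),
      fill = "firebrick", alpha = 0.35, colour = "firebrick"
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(
      title = "Decision space on the allocation simplex",
      subtitle = sprintf("supply %g over 3 options; red: min-max cuts", s)
    )
  if (!is.null(points)) {
    pxy <- ternary_xy(points, s)
    p <- p + ggplot2::geom_point(
      data = pxy, ggplot2::aes(x = .data$px, y = .data$py),
      colour = "black", size = 2
    )
  }
  p
}

#' Observed-versus-predicted scatter for a cohort evaluation
#'
#' Plots the stacked observed final opinions against the stacked model
#' predictions with the identity line; the pooled correlation is the
#' evaluation criterion.
#'
#' @param object A `cohort_evaluation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_evaluation <- function(object, ...) {
  df <- tibble::tibble(observed = object$obs_stack,
                       predicted = object$pred_stack)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(
      x = "predicted final opinion",
      y = "observed final opinion",
      title = sprintf(
        "Observed vs predicted final opinions (rho = %.3f, n = %d)",
        object$rho_final, object$n_stacked
      )
    ) +
    ggplot2::theme_minimal()
}

#' Recovery-curve plot
#'
#' Pooled observed-predicted correlation as a function of the observation
#' noise applied to the simulated finals.
#'
#' @param object An `fj_recovery` tibble from [recovery_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fj_recovery <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object[, c("noise_sd", "rho_final", "rho_changes")],
    cols = c("rho_final", "rho_changes"),
    names_to = "quantity", values_to = "rho"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$noise_sd, y = .data$rho,
                                   colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "observation noise sd (allocation units)",
      y = "pooled correlation",
      title = "Prediction recovery under observation noise"
    ) +
    ggplot2::theme_minimal()
}
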