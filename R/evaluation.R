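# Observed-versus-predicted evaluation: column-stacked correlations across a
# cohort of groups, in-decision-space fractions, consensus classification,
# and the 2x2 independence test for the two-part task.

#' Stack an opinion matrix column-wise / recover it
#'
#' The evaluation criterion is the linear correspondence of the *stacked*
#' observed and predicted opinion arrays: because the dynamics act on each
#' allocation dimension independently, the columns of an n x m array can be
#' concatenated (members within column, columns in dimension order) into one
#' vector without changing the predictions. Across a cohort, group blocks
#' are concatenated in cohort order.
#'
#' @param X n x m numeric matrix.
#' @return For `stack_columns`, a numeric vector of length `n * m`; for
#'   `unstack_columns`, the n x m matrix it came from.
#' @examples
#' stack_columns(rbind(c(1, 2), c(3, 4)))
#' unstack_columns(c(1, 3, 2, 4), n = 2)
#' @export
stack_columns <- function(X) {
  as.vector(as.matrix(X))
}

#' @rdname stack_columns
#' @param v Stacked vector of length `n * m`.
#' @param n Number of members (rows).
#' @export
unstack_columns <- function(v, n) {
  if (length(v) %% n != 0) abort("`length(v)` must be a multiple of `n`.")
  matrix(v, nrow = n)
}

#' Product-moment correlation with a t-test p-value
#'
#' Pearson's rho between stacked observed and predicted vectors, with the
#' two-sided p-value from `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom. A degenerate input (zero variance on either side,
#' e.g. a cohort in which no opinion changed) has no defined correlation and
#' raises a flagged error rather than silently returning 0 or NaN.
#'
#' @param obs,pred Numeric vectors of equal length `>= 3`.
#' @return A one-row tibble with columns `rho`, `p`, `n`.
#' @examples
#' pearson_with_p(c(1, 2, 3, 4), c(1, 2, 3, 5))
#' @export
pearson_with_p <- function(obs, pred) {
  obs <- as.numeric(obs)
  pred <- as.numeric(pred)
  if (length(obs) != length(pred)) abort("`obs` and `pred` must have equal length.")
  if (length(obs) < 3) abort("need at least 3 paired observations.")
  if (anyNA(obs) || anyNA(pred)) abort("inputs must not contain NA.")
  if (stats::sd(obs) == 0 || stats::sd(pred) == 0) {
    abort("zero variance: the correlation is undefined for this input.",
          class = "fjalloc_degenerate_correlation")
  }
  ct <- cor.test(obs, pred, method = "pearson", alternative = "two.sided")
  tibble::tibble(
    rho = unname(ct$estimate),
    p = ct$p.value,
    n = length(obs)
  )
}

#' Has a group reached consensus?
#'
#' True iff on every dimension the spread of members' positions (max minus
#' min) is at most `delta`. The default treats only identical recorded
#' positions as consensus -- members who agree record the same numbers --
#' while noisy synthetic observations call for a looser `delta`.
#'
#' @param X n x m matrix of final positions.
#' @param delta Consensus tolerance in allocation units.
#' @return Logical flag.
#' @examples
#' consensus_reached(rbind(c(50, 30, 20), c(50, 30, 20)))
#' consensus_reached(rbind(c(50, 30, 20), c(40, 40, 20)), delta = 1)
#' @export
consensus_reached <- function(X, delta = 1e-6) {
  X <- as.matrix(X)
  if (nrow(X) < 2) abort("consensus is defined for groups of at least 2 members.")
  spread <- apply(X, 2, function(col) max(col) - min(col))
  max(spread) <= delta
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact independence test for a 2x2 contingency table (e.g. consensus on
#' constraints versus consensus on an ideal position across groups): the
#' two-sided p-value sums, over all tables with the observed margins, the
#' hypergeometric probabilities no larger than that of the observed table.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_2x2(rbind(c(5, 5), c(5, 5)))
#' fisher_exact_2x2(rbind(c(10, 0), c(0, 10)))
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2))) abort("`table` must be 2x2.")
  if (anyNA(tab) || any(tab < 0)) abort("counts must be non-negative.")
  if (max(abs(tab - round(tab))) > 1e-9) abort("counts must be integers.")
  fisher.test(round(tab), alternative = "two.sided")$p.value
}

#' Predict equilibrium opinions for every group in a cohort
#'
#' Maps [fj_equilibrium()] over a cohort tibble: each group's influence
#' system is measured from its chip matrix and applied to its initial
#' opinion array. Adds list-columns `x_hat`, `v`, `changes` and a character
#' column `method` to the cohort.
#'
#' @param cohort Cohort tibble as produced by [generate_cohort()] or
#'   [read_cohort()]: one row per group with list-columns `x0` and `chips`.
#' @param max_iter,tol Iteration controls passed to [fj_equilibrium()].
#' @return The cohort tibble with prediction columns added.
#' @examples
#' cohort <- generate_cohort(n_groups = 2, seed = 1)
#' predict_opinions(cohort)
#' @export
predict_opinions <- function(cohort, max_iter = 1e5, tol = 1e-10) {
  check_cohort(cohort)
  preds <- purrr::map2(cohort$x0, cohort$chips, function(x0, chips) {
    fj_equilibrium(x0, influence_from_chips(chips),
                   max_iter = max_iter, tol = tol)
  })
  cohort$x_hat <- purrr::map(preds, "x_hat")
  cohort$v <- purrr::map(preds, "v")
  cohort$changes <- purrr::map(preds, "changes")
  cohort$method <- purrr::map_chr(preds, "method")
  cohort
}

check_cohort <- function(cohort, need_observed = FALSE) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0) {
    abort("`cohort` must be a data frame with at least one group.")
  }
  needed <- c("group_id", "n", "m", "supply", "simplex", "x0", "chips")
  missing <- setdiff(needed, names(cohort))
  if (length(missing) > 0) {
    abort(sprintf("`cohort` is missing column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  if (need_observed) {
    if (!"observed" %in% names(cohort)) {
      abort("`cohort` has no `observed` column; evaluation needs observed finals.")
    }
    no_obs <- purrr::map_lgl(cohort$observed, is.null)
    if (any(no_obs)) {
      abort(sprintf(
        "group '%s' has no observed final opinions.",
        cohort$group_id[which(no_obs)[1]]
      ), class = "fjalloc_missing_observed")
    }
  }
  invisible(cohort)
}

group_polytope <- function(x0, supply, simplex) {
  minmax_cuts(as.matrix(x0), supply = if (isTRUE(simplex)) supply else NA_real_)
}

#' Evaluate observed against predicted opinions across a cohort
#'
#' The full observed-versus-predicted methodology: stacks observed and
#' predicted final opinions (and opinion changes, observed final minus
#' recorded initial versus predicted equilibrium minus initial) across all
#' groups and dimensions, computes pooled Pearson correlations with t-test
#' p-values, classifies each member's observed final as inside or outside
#' the group's implicit min-max decision space, and counts consensus groups.
#'
#' Membership is always judged against the group's *implicit* polytope (the
#' min-max cuts of its own initial opinions); when a group carries an
#' explicit experiment-level box, membership in that box is reported as an
#' additional `in_box` column in the per-member records, since the implicit
#' polytope of initial opinions satisfying the box is already a subspace of
#' it.
#'
#' @param cohort Cohort tibble with observed finals; prediction columns are
#'   added via [predict_opinions()] if absent.
#' @param delta Consensus tolerance passed to [consensus_reached()].
#' @param tol Membership tolerance passed to [polytope_contains()].
#' @return An object of class `cohort_evaluation`; see [glance.cohort_evaluation()]
#'   for the one-row summary and [tidy.cohort_evaluation()] for per-member
#'   records.
#' @examples
#' cohort <- generate_cohort(n_groups = 3, noise_sd = 0, seed = 1)
#' ev <- evaluate_cohort(cohort)
#' glance(ev)
#' @export
evaluate_cohort <- function(cohort, delta = 1e-6, tol = 1e-6) {
  check_cohort(cohort, need_observed = TRUE)
  if (!"x_hat" %in% names(cohort)) cohort <- predict_opinions(cohort)

  obs_stack <- unlist(purrr::map(cohort$observed, stack_columns))
  pred_stack <- unlist(purrr::map(cohort$x_hat, stack_columns))
  init_stack <- unlist(purrr::map(cohort$x0, stack_columns))

  safe_pearson <- function(a, b) {
    tryCatch(
      pearson_with_p(a, b),
      fjalloc_degenerate_correlation = function(e) {
        tibble::tibble(rho = NA_real_, p = NA_real_, n = length(a))
      }
    )
  }
  cor_final <- safe_pearson(obs_stack, pred_stack)
  cor_changes <- safe_pearson(obs_stack - init_stack, pred_stack - init_stack)

  has_box <- "box" %in% names(cohort)
  records <- purrr::pmap_dfr(
    list(seq_len(nrow(cohort))),
    function(g) {
      x0 <- as.matrix(cohort$x0[[g]])
      obs <- as.matrix(cohort$observed[[g]])
      pred <- as.matrix(cohort$x_hat[[g]])
      poly <- group_polytope(x0, cohort$supply[g], cohort$simplex[g])
      box <- if (has_box) cohort$box[[g]] else NULL
      n <- nrow(x0)
      m <- ncol(x0)
      rec <- tibble::tibble(
        group_id = cohort$group_id[g],
        member = seq_len(n),
        in_space = vapply(seq_len(n), function(i) {
          polytope_contains(poly, obs[i, ], tol = tol)
        }, logical(1)),
        pred_in_space = vapply(seq_len(n), function(i) {
          polytope_contains(poly, pred[i, ], tol = tol)
        }, logical(1)),
        consensus = consensus_reached(obs, delta = delta)
      )
      if (!is.null(box)) {
        rec$in_box <- vapply(seq_len(n), function(i) {
          polytope_contains(box, obs[i, ], tol = tol)
        }, logical(1))
      }
      for (j in seq_len(m)) rec[[paste0("initial_", j)]] <- x0[, j]
      for (j in seq_len(m)) rec[[paste0("observed_", j)]] <- obs[, j]
      for (j in seq_len(m)) rec[[paste0("predicted_", j)]] <- pred[, j]
      rec
    }
  )

  consensus_by_group <- dplyr::distinct(
    records, .data$group_id, .data$consensus
  )

  structure(
    list(
      rho_final = cor_final$rho,
      rho_changes = cor_changes$rho,
      p_final = cor_final$p,
      p_changes = cor_changes$p,
      n_stacked = length(obs_stack),
      frac_in_space = mean(records$in_space),
      pred_frac_in_space = mean(records$pred_in_space),
      consensus_groups = sum(consensus_by_group$consensus),
      total_groups = nrow(cohort),
      delta = delta,
      tol = tol,
      records = records,
      obs_stack = obs_stack,
      pred_stack = pred_stack,
      init_stack = init_stack
    ),
    class = "cohort_evaluation"
  )
}

#' @export
print.cohort_evaluation <- function(x, ...) {
  cat(sprintf("<cohort_evaluation: %d groups, %d stacked observations>\n",
              x$total_groups, x$n_stacked))
  cat(sprintf("  rho (final positions): %.4f  (p = %.3g)\n", x$rho_final, x$p_final))
  cat(sprintf("  rho (opinion changes): %.4f  (p = %.3g)\n", x$rho_changes, x$p_changes))
  cat(sprintf("  final positions in decision space: %.1f%%\n",
              100 * x$frac_in_space))
  cat(sprintf("  consensus reached in %d of %d groups (delta = %g)\n",
              x$consensus_groups, x$total_groups, x$delta))
  invisible(x)
}

#' Tidy and summarise a cohort evaluation
#'
#' `tidy()` returns the per-member records: group and member ids,
#' per-dimension initial/observed/predicted positions, whether the observed
#' and predicted finals lie in the group's implicit decision space, the
#' group's consensus flag, and (when explicit experiment bounds were given)
#' membership in that box. `glance()` returns the one-row cohort summary.
#'
#' @param x A `cohort_evaluation` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cohort_evaluation <- function(x, ...) {
  x$records
}

#' @rdname tidy.cohort_evaluation
#' @export
glance.cohort_evaluation <- function(x, ...) {
  tibble::tibble(
    rho_final = x$rho_final,
    rho_changes = x$rho_changes,
    p_final = x$p_final,
    p_changes = x$p_changes,
    n_stacked = x$n_stacked,
    frac_in_space = x$frac_in_space,
    consensus_groups = x$consensus_groups,
    total_groups = x$total_groups
  )
}

#' Write evaluation outputs to disk
#'
#' `write_evaluation_csv()` writes the flat per-member records (one row per
#' member, per-dimension initial/observed/predicted columns, in-space flag);
#' `write_evaluation_json()` writes the cohort summary.
#'
#' @param evaluation A `cohort_evaluation` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_evaluation_csv <- function(evaluation, path) {
  stopifnot(inherits(evaluation, "cohort_evaluation"))
  utils::write.csv(tidy(evaluation), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_evaluation_csv
#' @export
write_evaluation_json <- function(evaluation, path) {
  stopifnot(inherits(evaluation, "cohort_evaluation"))
  jsonlite::write_json(
    as.list(glance(evaluation)),
    path, auto_unbox = TRUE, digits = I(17)
  )
  invisible(path)
}

#' Prediction-recovery curve over observation noise
#'
#' Generates one seeded cohort, then simulates observed finals at each noise
#' level (equilibrium plus Gaussian measurement noise, projected back to the
#' simplex) and evaluates the cohort at that level. With the
#' Friedkin-Johnsen model as ground truth, the pooled correlation of
#' observed and predicted finals is exactly 1 at zero noise and degrades as
#' the noise grows -- the parameter-free recovery property of the pipeline.
#'
#' @param n_groups Number of groups in the cohort.
#' @param noise_levels Observation noise standard deviations (allocation
#'   units) at which to evaluate.
#' @param seed Integer seed; the cohort and every noise draw derive from it.
#' @param delta,tol Passed to [evaluate_cohort()].
#' @param ... Further arguments to [generate_cohort()].
#' @return A tibble of class `fj_recovery` with one row per noise level:
#'   `noise_sd`, `rho_final`, `rho_changes`, `frac_in_space`, `n_stacked`.
#' @examples
#' recovery_curve(n_groups = 10, noise_levels = c(0, 2), seed = 1)
#' @export
recovery_curve <- function(n_groups = 200, noise_levels = c(0, 1, 2, 5),
                           seed = 1, delta = 1e-6, tol = 1e-6, ...) {
  cohort <- generate_cohort(n_groups = n_groups, noise_sd = 0, seed = seed, ...)
  cohort <- predict_opinions(cohort)
  rows <- purrr::imap_dfr(noise_levels, function(sd, lev) {
    noisy <- cohort
    noisy$observed <- purrr::imap(
      seq_len(nrow(cohort)),
      function(g, idx) {
        simulate_observed_finals(
          cohort[g, ], noise_sd = sd,
          seed = derive_seed(seed, 7000L + 31L * lev + g)
        )
      }
    )
    ev <- evaluate_cohort(noisy, delta = delta, tol = tol)
    tibble::tibble(
      noise_sd = sd,
      rho_final = ev$rho_final,
      rho_changes = ev$rho_changes,
      frac_in_space = ev$frac_in_space,
      n_stacked = ev$n_stacked
    )
  })
  class(rows) <- c("fj_recovery", class(rows))
  rows
}
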