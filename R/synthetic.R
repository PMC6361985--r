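# Synthetic cohort generator. Emulates the laboratory allocation experiments:
# small groups (3-4 members) privately record initial allocation opinions on
# an m-option issue with supply s, discuss, record finals, and report their
# influence weights by distributing 100 chips over the group. The generator's
# ground truth for observed finals is the Friedkin-Johnsen equilibrium plus
# bounded measurement noise.

# deterministic sub-seed derivation; keeps every seed within 32-bit range
derive_seed <- function(seed, k) {
  as.integer((abs(as.numeric(seed)) %% 1e6) * 1009 + (k %% 1e6)) %% 2147483646L + 1L
}

# Dirichlet sampler via independent gammas (no installed package exports one)
rdirichlet <- function(n, alpha) {
  stopifnot(all(alpha > 0))
  x <- matrix(rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Round non-negative reals to integers preserving their total
#'
#' Largest-remainder rounding: floor every entry, then hand the remaining
#' units to the entries with the largest fractional parts (ties to the
#' earlier index). Used to integerize chip allocations so rows sum to
#' exactly 100.
#'
#' @param x Non-negative numeric vector.
#' @param total Target integer total; defaults to `round(sum(x))`.
#' @return Integer vector of `length(x)` summing to `total`.
#' @examples
#' largest_remainder_round(c(33.4, 33.3, 33.3))
#' @export
largest_remainder_round <- function(x, total = round(sum(x))) {
  x <- as.numeric(x)
  if (any(x < 0)) abort("`x` must be non-negative.")
  if (abs(sum(x) - total) > 0.5 + 1e-9) {
    x <- x * total / sum(x)
  }
  base <- floor(x)
  short <- as.integer(round(total - sum(base)))
  if (short > 0) {
    give <- order(x - base, decreasing = TRUE)[seq_len(short)]
    base[give] <- base[give] + 1
  }
  as.integer(base)
}

draw_chips <- function(n, self_chips_range = c(30, 80)) {
  chips <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    self_choices <- seq(self_chips_range[1], self_chips_range[2])
    self <- self_choices[sample.int(length(self_choices), 1)]
    others <- setdiff(seq_len(n), i)
    share <- drop(rdirichlet(1, rep(1, n - 1)))
    row <- numeric(n)
    row[i] <- self
    row[others] <- (100 - self) * share
    chips[i, ] <- largest_remainder_round(row, total = 100)
  }
  chips
}

draw_initial_opinions <- function(n, m, supply, alpha, box = NULL,
                                  max_tries = 10000) {
  if (is.null(alpha)) alpha <- rep(3, m)
  if (length(alpha) == 1) alpha <- rep(alpha, m)
  stopifnot(length(alpha) == m, all(alpha > 0))
  X <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      x <- drop(rdirichlet(1, alpha)) * supply
      if (is.null(box) || polytope_contains(box, x, tol = 0)) {
        X[i, ] <- x
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort("could not draw an initial opinion inside the given box; is it feasible for this supply?")
    }
  }
  X
}

new_group_record <- function(group_id, x0, chips, supply, simplex,
                             experiment_kind, observed = NULL, box = NULL) {
  tibble::tibble(
    group_id = group_id,
    n = nrow(x0),
    m = ncol(x0),
    supply = supply,
    experiment_kind = experiment_kind,
    simplex = simplex,
    x0 = list(unname(x0)),
    chips = list(unname(chips)),
    observed = list(observed),
    box = list(box)
  )
}

#' Generate one synthetic group
#'
#' Draws a group record emulating one laboratory group: heterogeneous
#' initial allocation opinions from a Dirichlet law scaled to the supply
#' (rejection-resampled into `box` when explicit experiment bounds are
#' given), and a 100-chip influence self-report per member (self-chips
#' uniform on the configured range, the remainder split among the others by
#' a symmetric Dirichlet draw, integerized by largest-remainder rounding so
#' every row sums to exactly 100).
#'
#' @param n Group size (laboratory groups had 3-4 members).
#' @param m Number of allocation dimensions.
#' @param supply Allocation total `s` (percent scale: 100).
#' @param alpha Dirichlet concentration for initial opinions: a scalar or
#'   m-vector. The default `rep(3, m)` gives moderately dispersed initial
#'   preferences around an even split.
#' @param box Optional [decision_polytope()] of explicit experiment bounds
#'   that initial opinions must satisfy.
#' @param self_chips_range Integer range from which each member's self-chip
#'   count is drawn uniformly; most subjects retain substantial self-weight.
#' @param noise_sd Observation noise (allocation units) for the simulated
#'   observed finals; `NULL` leaves the group without observed finals.
#' @param seed Optional integer seed (applied locally; the global RNG state
#'   is untouched).
#' @param group_id Identifier string.
#' @return A one-row cohort tibble (see [generate_cohort()]).
#' @examples
#' generate_group(n = 3, m = 3, seed = 1)
#' @export
generate_group <- function(n = 3, m = 3, supply = 100, alpha = NULL,
                           box = NULL, self_chips_range = c(30, 80),
                           noise_sd = NULL, seed = NULL,
                           group_id = "g1") {
  stopifnot(n >= 2, m >= 2, supply > 0)
  if (!is.null(box)) {
    stopifnot(inherits(box, "decision_polytope"))
    if (is_empty(box)) abort("`box` is infeasible for this supply.")
  }
  draw <- function() {
    x0 <- draw_initial_opinions(n, m, supply, alpha, box = box)
    chips <- draw_chips(n, self_chips_range)
    grp <- new_group_record(group_id, x0, chips, supply, simplex = TRUE,
                            experiment_kind = if (is.null(box)) "unconstrained" else "given_constraints",
                            box = box)
    if (!is.null(noise_sd)) {
      grp$observed <- list(simulate_observed_finals(grp, noise_sd = noise_sd))
    }
    grp
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate observed final opinions for a group
#'
#' The ground truth is the Friedkin-Johnsen equilibrium of the group's
#' measured influence system; observation is that equilibrium plus
#' independent zero-mean Gaussian noise per entry, projected back onto the
#' allocation simplex by clipping negatives to zero and rescaling each row
#' to the supply (for non-simplex constraint opinions, values are clipped to
#' `[0, supply-scale]` without rescaling). At `noise_sd = 0` the observed
#' finals are the equilibrium exactly.
#'
#' @param group One-row cohort tibble (a group record).
#' @param noise_sd Noise standard deviation in allocation units.
#' @param seed Optional integer seed (applied locally).
#' @return n x m matrix of observed final opinions.
#' @examples
#' g <- generate_group(seed = 1)
#' simulate_observed_finals(g, noise_sd = 2, seed = 2)
#' @export
simulate_observed_finals <- function(group, noise_sd = 0, seed = NULL) {
  stopifnot(is.data.frame(group), nrow(group) == 1, noise_sd >= 0)
  x0 <- as.matrix(group$x0[[1]])
  pred <- fj_equilibrium(x0, influence_from_chips(group$chips[[1]]))
  x_hat <- pred$x_hat
  if (noise_sd == 0) return(x_hat)
  add_noise <- function() {
    obs <- x_hat + matrix(rnorm(length(x_hat), sd = noise_sd),
                          nrow(x_hat), ncol(x_hat))
    if (isTRUE(group$simplex[1])) {
      obs <- pmax(obs, 0)
      rs <- rowSums(obs)
      for (i in seq_len(nrow(obs))) {
        if (rs[i] <= 0) {
          obs[i, ] <- x_hat[i, ]  # degenerate draw: fall back to the equilibrium
        } else {
          obs[i, ] <- obs[i, ] * group$supply[1] / rs[i]
        }
      }
    } else {
      hi <- if (is.na(group$supply[1])) 100 else group$supply[1]
      obs <- pmin(pmax(obs, 0), hi)
    }
    obs
  }
  if (is.null(seed)) add_noise() else withr::with_seed(seed, add_noise())
}

#' Generate a synthetic cohort of groups
#'
#' Reproducibly draws `n_groups` group records with sizes sampled from
#' `sizes` (laboratory cohorts nested 3-4 members per group, e.g. 118
#' individuals in 34 groups). Each group gets its own RNG stream derived
#' from `seed`, so generating a cohort and generating any single group of it
#' in isolation agree, and groups are statistically uncoupled.
#'
#' @param n_groups Number of groups.
#' @param sizes Candidate group sizes, sampled uniformly per group.
#' @param m,supply,alpha,box,self_chips_range Passed to [generate_group()].
#' @param noise_sd Observation noise for simulated observed finals
#'   (allocation units); the default 2 emulates members recording integers
#'   near, but not exactly at, their settled positions. Use `NULL` to leave
#'   observed finals absent.
#' @param seed Integer seed for the whole cohort.
#' @param experiment_kind Overrides the kind tag on every group if given.
#' @return A cohort tibble: one row per group with columns `group_id`, `n`,
#'   `m`, `supply`, `experiment_kind`, `simplex`, and list-columns `x0`
#'   (n x m initial opinions), `chips` (n x n integer chip matrix),
#'   `observed` (n x m observed finals or `NULL`), `box` (explicit bounds or
#'   `NULL`).
#' @examples
#' generate_cohort(n_groups = 3, seed = 1)
#' @export
generate_cohort <- function(n_groups, sizes = c(3, 4), m = 3, supply = 100,
                            alpha = NULL, box = NULL,
                            self_chips_range = c(30, 80), noise_sd = 2,
                            seed = 1, experiment_kind = NULL) {
  stopifnot(n_groups >= 1, length(sizes) >= 1)
  group_sizes <- withr::with_seed(
    derive_seed(seed, 1L),
    sample(sizes, n_groups, replace = TRUE)
  )
  cohort <- purrr::map_dfr(seq_len(n_groups), function(g) {
    grp <- generate_group(
      n = group_sizes[g], m = m, supply = supply, alpha = alpha, box = box,
      self_chips_range = self_chips_range, noise_sd = noise_sd,
      seed = derive_seed(seed, 100L + g), group_id = sprintf("g%d", g)
    )
    grp
  })
  if (!is.null(experiment_kind)) cohort$experiment_kind <- experiment_kind
  cohort
}

#' Generate a two-part constraints-then-ideal group
#'
#' Emulates the two-part task in which a group first seeks consensus on a
#' set of per-dimension min/max constraints and then on an ideal allocation
#' satisfying them. Each member draws an ideal position on the `m = 3`
#' allocation simplex and idiosyncratic half-widths around it, producing a
#' 6-value constraint opinion `(min_1, min_2, min_3, max_1, max_2, max_3)`
#' with `min_j <= ideal_j <= max_j` by construction (clipped to `[0, 100]`).
#' The constraints task is a non-simplex opinion array (the 6 values need
#' not sum to anything); the ideal task is simplex-constrained.
#'
#' @param n Group size.
#' @param supply Allocation total for the ideal task.
#' @param alpha Dirichlet concentration for ideal positions.
#' @param width_range Range from which per-dimension half-widths are drawn
#'   uniformly (allocation units).
#' @param share_chips If `TRUE` (default) the same chip matrix measures the
#'   influence system for both tasks; otherwise each task draws its own.
#' @param self_chips_range,noise_sd,seed As in [generate_group()].
#' @param group_id Identifier string.
#' @return A list with one-row cohort tibbles `constraints` (m = 6,
#'   non-simplex, kind `"two_part_constraints"`) and `ideals` (m = 3,
#'   simplex, kind `"two_part_ideals"`).
#' @examples
#' generate_two_part_group(n = 3, seed = 1)
#' @export
generate_two_part_group <- function(n = 3, supply = 100, alpha = NULL,
                                    width_range = c(5, 20),
                                    share_chips = TRUE,
                                    self_chips_range = c(30, 80),
                                    noise_sd = NULL, seed = NULL,
                                    group_id = "g1") {
  m <- 3  # the two-part food-groups task is three-dimensional
  draw <- function() {
    ideals <- draw_initial_opinions(n, m, supply, alpha)
    lo_w <- matrix(runif(n * m, width_range[1], width_range[2]), n, m)
    hi_w <- matrix(runif(n * m, width_range[1], width_range[2]), n, m)
    mins <- pmax(ideals - lo_w, 0)
    maxs <- pmin(ideals + hi_w, supply)
    constraints_x0 <- cbind(mins, maxs)
    chips1 <- draw_chips(n, self_chips_range)
    chips2 <- if (share_chips) chips1 else draw_chips(n, self_chips_range)
    con <- new_group_record(group_id, constraints_x0, chips1, NA_real_,
                            simplex = FALSE,
                            experiment_kind = "two_part_constraints")
    ide <- new_group_record(group_id, ideals, chips2, supply,
                            simplex = TRUE,
                            experiment_kind = "two_part_ideals")
    if (!is.null(noise_sd)) {
      con$observed <- list(simulate_observed_finals(con, noise_sd = noise_sd))
      ide$observed <- list(simulate_observed_finals(ide, noise_sd = noise_sd))
    }
    list(constraints = con, ideals = ide)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate a two-part cohort
#'
#' @inheritParams generate_cohort
#' @param width_range,share_chips Passed to [generate_two_part_group()].
#' @return A list with cohort tibbles `constraints` and `ideals`, row `g` of
#'   each describing the same group on its two tasks.
#' @examples
#' generate_two_part_cohort(n_groups = 2, seed = 1)
#' @export
generate_two_part_cohort <- function(n_groups, sizes = c(3, 4), supply = 100,
                                     alpha = NULL, width_range = c(5, 20),
                                     share_chips = TRUE,
                                     self_chips_range = c(30, 80),
                                     noise_sd = 2, seed = 1) {
  stopifnot(n_groups >= 1)
  group_sizes <- withr::with_seed(
    derive_seed(seed, 2L),
    sample(sizes, n_groups, replace = TRUE)
  )
  parts <- purrr::map(seq_len(n_groups), function(g) {
    generate_two_part_group(
      n = group_sizes[g], supply = supply, alpha = alpha,
      width_range = width_range, share_chips = share_chips,
      self_chips_range = self_chips_range, noise_sd = noise_sd,
      seed = derive_seed(seed, 500L + g), group_id = sprintf("g%d", g)
    )
  })
  list(
    constraints = purrr::map_dfr(parts, "constraints"),
    ideals = purrr::map_dfr(parts, "ideals")
  )
}

#' Cross-classify consensus on constraints versus consensus on ideals
#'
#' Builds the 2x2 table of groups by whether they reached consensus on the
#' constraints task and on the ideal-position task, the input to
#' [fisher_exact_2x2()] for testing whether the two are independent.
#'
#' @param constraints_cohort,ideals_cohort Matching cohort tibbles from
#'   [generate_two_part_cohort()] (or real data in the same shape), with
#'   observed finals.
#' @param delta Consensus tolerance.
#' @return 2x2 integer matrix with rows = constraints consensus (yes/no) and
#'   columns = ideals consensus (yes/no).
#' @export
two_part_consensus_table <- function(constraints_cohort, ideals_cohort,
                                     delta = 1e-6) {
  stopifnot(nrow(constraints_cohort) == nrow(ideals_cohort))
  con <- purrr::map_lgl(constraints_cohort$observed, consensus_reached,
                        delta = delta)
  ide <- purrr::map_lgl(ideals_cohort$observed, consensus_reached,
                        delta = delta)
  tab <- matrix(
    c(sum(con & ide), sum(con & !ide), sum(!con & ide), sum(!con & !ide)),
    2, 2, byrow = TRUE,
    dimnames = list(
      constraints = c("consensus", "dissensus"),
      ideals = c("consensus", "dissensus")
    )
  )
  tab
}
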