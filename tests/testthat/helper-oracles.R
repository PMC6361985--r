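# Independent oracles and random-instance generators used across the suite.
# Each oracle is a definitional computation written independently of the
# implementation path it checks.

# random row-stochastic W with strictly positive diagonal (so every member
# keeps some self-weight and the FJ closed form is well conditioned)
random_influence_system <- function(n, min_self = 0.2) {
  raw <- matrix(rgamma(n * n, shape = 1), n, n)
  raw <- raw / rowSums(raw)
  W <- min_self * diag(n) + (1 - min_self) * raw
  influence_system(W)
}

# random simplex-constrained initial opinion array
random_opinions <- function(n, m, supply = 100, alpha = 1) {
  X <- matrix(rgamma(n * m, shape = alpha), n, m)
  X / rowSums(X) * supply
}

# random nonempty box-on-simplex polytope built from min-max cuts of random
# simplex points (nonempty by construction)
random_polytope <- function(m, n_points = 4, supply = 100) {
  minmax_cuts(random_opinions(n_points, m, supply))
}

# exhaustive pin-pattern vertex oracle: for every subset of m - 1 pinned
# coordinates and every lower/upper assignment, solve the free coordinate
# from the supply equality and keep feasible solutions (written with
# expand.grid over all m coordinates' pin states, independently of the
# implementation's loop structure)
oracle_vertices <- function(p, tol = 1e-8) {
  m <- p$m
  states <- expand.grid(rep(list(c("lo", "hi", "free")), m),
                        stringsAsFactors = FALSE)
  keep <- apply(states, 1, function(st) sum(st == "free") == 1)
  states <- states[keep, , drop = FALSE]
  out <- list()
  for (r in seq_len(nrow(states))) {
    st <- as.character(states[r, ])
    x <- ifelse(st == "lo", p$lower, ifelse(st == "hi", p$upper, NA))
    f <- which(st == "free")
    x[f] <- p$supply - sum(x[-f])
    if (x[f] >= p$lower[f] - tol && x[f] <= p$upper[f] + tol) {
      out[[length(out) + 1]] <- x
    }
  }
  V <- unique(do.call(rbind, out))
  # collapse near-duplicates in max-norm
  keep <- rep(TRUE, nrow(V))
  for (i in seq_len(nrow(V))) {
    if (!keep[i] || i == nrow(V)) next
    for (j in (i + 1):nrow(V)) {
      if (keep[j] && max(abs(V[i, ] - V[j, ])) <= tol) keep[j] <- FALSE
    }
  }
  V <- V[keep, , drop = FALSE]
  V[do.call(order, as.data.frame(V)), , drop = FALSE]
}

# dense-grid brute-force LP maximizer over {l <= x <= u, sum(x) = s}, m = 3
oracle_lp_grid <- function(objective, p, step) {
  best <- -Inf
  best_x <- NULL
  for (x1 in seq(p$lower[1], p$upper[1], by = step)) {
    for (x2 in seq(p$lower[2], p$upper[2], by = step)) {
      x3 <- p$supply - x1 - x2
      if (x3 < p$lower[3] - 1e-12 || x3 > p$upper[3] + 1e-12) next
      val <- sum(objective * c(x1, x2, x3))
      if (val > best) {
        best <- val
        best_x <- c(x1, x2, x3)
      }
    }
  }
  list(x = best_x, value = best)
}

# definitional product-moment correlation with the t-based two-sided p
oracle_pearson <- function(obs, pred) {
  n <- length(obs)
  num <- sum((obs - mean(obs)) * (pred - mean(pred)))
  den <- sqrt(sum((obs - mean(obs))^2) * sum((pred - mean(pred))^2))
  rho <- num / den
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * pt(-abs(t), df = n - 2)
  list(rho = rho, p = p)
}

# full hypergeometric enumeration of the two-sided Fisher p-value: sum the
# probabilities of all tables with the observed margins whose probability
# does not exceed that of the observed table
oracle_fisher <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  N <- sum(tab)
  lo <- max(0, r1 + c1 - N)
  hi <- min(r1, c1)
  probs <- dhyper(lo:hi, c1, N - c1, r1)
  p_obs <- dhyper(a, c1, N - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# pull the coordinate columns of an enumerate_vertices() tibble as a matrix
vertex_matrix_for_test <- function(verts) {
  as.matrix(verts[, grep("^x", names(verts)), drop = FALSE])
}
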