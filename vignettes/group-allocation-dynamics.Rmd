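---
title: "Opinion dynamics and implicit decision spaces in group resource allocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Opinion dynamics and implicit decision spaces in group resource allocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fjalloc)
```

## The problem

Small groups routinely decide how to split a fixed supply of a resource —
money, positions, percentages of a diet — over a handful of options. A
member's opinion on an m-option allocation issue is a vector
$\mathbf{x}_i = (x_{i1}, \dots, x_{im})$ with $x_{ij} \ge 0$ and
$\sum_j x_{ij} = s$: a point on the supply-$s$ simplex. fjalloc implements
a complete analysis pipeline for such decisions:

* **dynamics** — the Friedkin–Johnsen (FJ) model of opinion change under
  interpersonal influence, with the DeGroot model as its fully-susceptible
  special case;
* **geometry** — the implicit decision space that a group's initial
  opinions automatically cut on the simplex, with exact vertex enumeration
  and convex-hull membership;
* **allocation LP** — the optimisation variant of the task, solved exactly
  over that polytope;
* **evaluation** — the observed-versus-predicted methodology (stacked
  correlations, in-decision-space fractions, consensus counts, Fisher's
  exact independence test);
* **synthetic data** — a seeded generator of laboratory-style cohorts, so
  the whole pipeline is testable end to end without human-subject data.

## The influence model

Each member $i$ distributes influence weights $w_{ij} \in [0,1]$,
$\sum_j w_{ij} = 1$, over the group (self included). Pure iterative
weighted averaging — the DeGroot model — updates
$x_i(k+1) = \sum_j w_{ij} x_j(k)$. The FJ generalisation lets members keep
an ongoing attachment to their initial opinion:

$$X(k+1) = A W X(k) + (I - A)\,X(0), \qquad A = \mathrm{diag}(a_{11},\dots,a_{nn}),\; a_{ii} = 1 - w_{ii}.$$

A member with $a_{ii} = 0$ never moves; a member with $a_{ii} = 1$ has no
anchorage and averages freely. When $I - AW$ is invertible the settled
opinions have the closed form

$$\hat X = V X(0), \qquad V = (I - AW)^{-1}(I - A),$$

with $V$ row-stochastic: each member's equilibrium opinion is a convex
combination of the group's initial opinions, so row sums (the supply) are
preserved and no prediction can leave the convex hull of the initial
opinion array. The predicted net changes are $\hat X - X(0)$.

Influence weights are *measured*, not fitted: each member reports a
100-chip allocation over the group, and `weights_from_chips()` normalises
each row by its own total (totals that miss 100 through arithmetic slips
are a relative measure anyway; an all-zero row is rejected as unusable).
There are no free parameters anywhere in the prediction.

```{r}
sys <- influence_from_chips(rbind(c(50, 50), c(50, 50)))
total_influence(sys)
fj_equilibrium(matrix(c(0, 100), 2, 1), sys)$x_hat
```

### Numerical choices

* **Closed form vs iteration.** `fj_equilibrium()` uses the closed form
  when the reciprocal condition estimate of $I - AW$ is at least
  `1e-12`, and otherwise falls back to fixed-point iteration (default
  `tol = 1e-10`, `max_iter = 1e5`; the contraction rate is
  $\max_i a_{ii}$, so convergence is slow only when some member is almost
  fully susceptible). The fallback is not an edge case: with $A = I$ the
  matrix $I - W$ is *always* singular because $W$ is row-stochastic, so
  every DeGroot computation takes the iterative path. Non-convergence
  (a genuinely periodic network such as two members who each put all
  weight on the other) is reported on the trajectory, not raised.
* **$A$ is derived.** Measured systems always set $a_{ii} = 1 - w_{ii}$;
  the only way to obtain $A = I$ is the explicit `degroot_system()`
  constructor, which exists because the DeGroot limit is a model of
  interest in its own right.
* **Validation.** Rows of $W$ must sum to 1 within `1e-9` and simplex
  opinion rows to $s$ within the same tolerance; invalid inputs are
  rejected rather than silently renormalised (chips being the one
  documented exception).
* **Consensus certificate.** `degroot_consensus_certificate()` certifies
  consensus from a globally reachable node plus the standard sufficient
  aperiodicity condition $w_{ii} > 0\ \forall i$. Aperiodicity can hold
  without positive self-weights, so networks with a reachable node but a
  zero self-weight are labelled *undetermined* (`NA`) rather than decided
  either way.

## The implicit decision space

A group's initial opinions automatically cut a polytope on the simplex:
on each dimension, the coordinate-wise minimum and maximum of the members'
initial values bound the candidate allocations,

$$\{\,x : l_j \le x_j \le u_j,\ x_j \ge 0,\ \textstyle\sum_j x_j = s\,\}.$$

Every decision space in this setting is a box intersected with one
hyperplane, so the H-representation is kept as bounds plus one equality —
no general half-space machinery — and vertex enumeration is exact: at a
vertex, $m-1$ coordinates are pinned at a bound and the supply equality
determines the last, so `enumerate_vertices()` checks all
$m \cdot 2^{m-1}$ pin patterns, keeps feasible candidates, and
deduplicates coincident corners in max-norm at `1e-8` (pin patterns can
coincide at degenerate corners). Intended for $m \le 6$; all tasks here
have $m \in \{3, 4, 6\}$.

```{r}
amdr <- decision_polytope(c(45, 10, 20), c(65, 35, 35), supply = 100)
enumerate_vertices(amdr)
```

Other choices:

* **Lower bounds are clipped at 0** on construction (allocations are
  non-negative); emptiness is decidable from
  $\sum_j l_j \le s \le \sum_j u_j$ and $l \le u$.
* **Membership tolerance** defaults to `1e-6` allocation units. The data
  the check is designed for are integer percentages, so the tolerance is
  loose relative to machine precision and exposed as a parameter: nothing
  in the task fixes how close a recorded final must be to count as "on"
  the decision space, and the default treats only essentially exact
  membership as membership.
* **Pure boxes.** Min/max *constraint* opinions (the two-part task below)
  are bounds, not allocations, and obey no sum constraint; a
  `decision_polytope()` with `supply = NA` drops the equality from the
  membership check, and vertex enumeration (which needs the equality) is
  not defined for it.
* **Hull membership** is solved exactly for group-sized point sets via
  Carathéodory's theorem: a point of the hull is a convex combination of
  at most $m+1$ affinely independent generators, so every such subset's
  barycentric system is solved directly. The hull is contained in the
  min-max polytope, generally strictly — the polytope is the analysis's
  bounded-rationality object, the hull is what weighted averaging can
  actually reach.

## The optimisation variant

With a known linear payoff the task is a linear program over the same
polytope. Since the feasible set is a bounded polytope, an optimum lies at
a vertex; `solve_allocation_lp()` scores every enumerated vertex, which is
exact at these dimensions. Ties (e.g. a constant objective) are collected
within a `1e-9` relative tolerance and broken deterministically by
lexicographic order. `grade_solution()` classifies a proposed answer by
feasibility and payoff gap, with a default optimality tolerance of `1e-6`
payoff units — generous against answers recorded as two-decimal fractions.

```{r}
lp <- allocation_lp(
  c(1.25, 1.50, 1.75),
  decision_polytope(c(0.45, 0.10, 0.20), c(0.65, 0.35, 0.35), supply = 1)
)
solve_allocation_lp(lp)
grade_solution(lp, c(0.65, 0.15, 0.20))
```

## Evaluation methodology

Because the dynamics act column-wise, an $n \times m$ opinion array can be
stacked column-major into one vector without changing the predictions;
`evaluate_cohort()` pools stacked observed and predicted finals (and
changes, always *observed final minus recorded initial* versus
$\hat X - X(0)$ — never trajectory increments) across all groups into
pooled Pearson correlations with two-sided t-test p-values. Zero-variance
stacks yield a flagged undefined correlation (`NA` with the degenerate
condition signalled), never a silent 0.

Membership fractions use each group's **implicit** polytope. When an
experiment additionally imposes explicit bounds, the implicit polytope of
compliant initial opinions is already a subspace of the given box, so the
box appears only as an optional `in_box` column in the per-member records.
Dissensus groups' members enter the fraction exactly like consensus
members.

Consensus is a spread test: all members within `delta` on every dimension.
The default `delta = 1e-6` treats only identical recorded finals as
consensus (members who agree write down the same numbers); noisy synthetic
observations call for a looser value, which every entry point exposes.

`fisher_exact_2x2()` performs the exact two-sided independence test
(summing hypergeometric probabilities no larger than the observed
table's) used to ask whether consensus on constraints is independent of
consensus on ideals in the two-part task.

## The synthetic generator

No subject-level data are distributed with the task descriptions, so the
generator emulates the laboratory design and is itself first-class, tested
code. Its defaults are the study conditions and were chosen once:

* **Groups of 3–4 members** (sizes sampled uniformly), $m = 3$ by default
  with $s = 100$ percent; a 34-group cohort then totals on the order of
  118 members, matching the nested design the analysis is meant for.
* **Initial opinions** are Dirichlet$(3, \dots, 3)$ draws scaled to $s$:
  moderately dispersed preferences around an even split (component
  standard deviation ≈ 14 points), heterogeneous enough to cut
  non-degenerate decision spaces. With explicit experiment bounds, draws
  are rejection-resampled into the box.
* **Chips**: self-chips uniform on $\{30, \dots, 80\}$ — most people
  retain substantial self-weight after a short discussion — with the
  remainder split over the others by a symmetric Dirichlet(1) draw and
  integerised by largest-remainder rounding so each row sums to exactly
  100.
* **Observed finals** are the FJ equilibrium plus i.i.d. Gaussian noise
  (default sd 2 allocation units, emulating members recording integers
  near their settled positions), projected back to the simplex by
  clipping negatives and rescaling the row to $s$. Clip-and-rescale is a
  modelling choice (it is not the Euclidean projection) made for
  simplicity and positivity. Noise is applied to observations only, never
  to $W$ or $X(0)$: measurement error on finals is the simplest stand-in
  for the error sources the model admits.
* **Two-part groups** draw each member's ideal on the simplex and
  idiosyncratic half-widths (uniform 5–20 units) around it, giving a
  6-value constraint opinion $(\min_1,\min_2,\min_3,\max_1,\max_2,\max_3)$
  with $\min_j \le \mathrm{ideal}_j \le \max_j$ by construction; the same
  chip matrix measures both tasks by default.
* **Determinism**: every group derives its own RNG stream from the cohort
  seed, so a cohort is byte-identically reproducible and a single group
  can be regenerated in isolation; library code never seeds the global
  RNG (all seeding is scoped).

What the generator does *not* emulate: discussion dynamics over time
(turn-taking, talk time), systematic reporting biases, exogenous
disturbances mid-discussion, or subjects whose updating is not weighted
averaging. Passing pipeline tests on synthetic cohorts therefore shows
internal consistency — the pipeline recovers the model that generated the
data, exactly at zero noise and gracefully under noise — not that real
groups follow the model.

```{r}
rc <- recovery_curve(n_groups = 20, noise_levels = c(0, 2, 5), seed = 1)
rc
```

At zero noise the pooled correlation is exactly 1 and every final lies in
its group's decision space (the convex-hull property makes this a theorem,
and the tests verify it at scale); correlations degrade monotonically as
observation noise grows.

## Problem sizes

The shipped tests and the reproduction script use 1,000 random influence
systems ($n \le 6$, $m \le 4$) for the equilibrium and row-stochasticity
properties, 1,000 noiseless synthetic groups for the containment property,
200 random polytopes for the vertex-enumeration cross-check, a 200-group
cohort over noise levels $\{0, 1, 2, 5\}$ for the recovery curve, and all
2×2 tables with margins ≤ 12 for the Fisher cross-check — sizes at which
every property is exercised far beyond the scale of a laboratory cohort
while the whole suite runs in about a minute.

## Known limitations

* Geometry is specialised to box-on-simplex polytopes; there is no
  general H/V conversion, no volume computation, and $m > 6$ vertex
  enumeration is deliberately out of scope.
* The LP solver handles exactly the bounded box-on-simplex feasible sets
  of the allocation task — no unbounded, equality-free, or integer
  problems.
* The consensus certificate is sufficient-only (undetermined cases are
  reported as such), and the consensus classification of noisy data
  depends on the chosen `delta`.
* The FJ model itself confines predictions to the convex hull of initial
  opinions; settled positions outside the hull are evidence against the
  mechanism and are exactly what the evaluation statistics are designed
  to surface.
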