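Package: fjalloc
Title: Friedkin-Johnsen Opinion Dynamics for Group Resource-Allocation Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing small-group decision-making on resource
    allocation distributions. Implements Friedkin-Johnsen and DeGroot opinion
    dynamics on multidimensional allocation opinions (iteration, closed-form
    equilibrium, total influence, consensus certificates), the implicit convex
    polytope decision space cut from the allocation simplex by a group's
    extremal initial preferences (membership, intersection, exact vertex
    enumeration, convex-hull containment), a vertex-enumeration solver for
    linear programs over that polytope, an observed-versus-predicted evaluation
    pipeline (stacked correlations, in-decision-space fractions, consensus
    classification, Fisher's exact test), and a synthetic cohort generator
    emulating laboratory allocation experiments with chip-measured influence
    networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
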