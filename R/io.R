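# Cohort serialization. JSON is the canonical interchange format (groups are
# ragged: n varies between 3 and 4, so a nested structure fits); CSV is a
# flat export only. Numbers are serialized at full precision so a write/read
# round trip is lossless.

COHORT_SCHEMA_VERSION <- "1.0"

allowed_group_fields <- c(
  "group_id", "n", "m", "supply", "experiment_kind", "simplex",
  "x0", "chips", "observed", "w", "box"
)

mat_to_rows <- function(M) {
  if (is.null(M)) return(NULL)
  lapply(seq_len(nrow(M)), function(i) unname(M[i, ]))
}

rows_to_mat <- function(rows) {
  if (is.null(rows)) return(NULL)
  do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r))))
}

#' Write / read a cohort file
#'
#' `write_cohort()` serializes a cohort tibble to a single JSON document
#' (`schema_version`, `experiment_kind`, and one record per group) at full
#' numeric precision; `read_cohort()` reads it back, validating the schema:
#' unknown fields are rejected with an error naming the field and group,
#' opinion rows must lie on the simplex when flagged as such, chip rows must
#' have positive totals, and an optional precomputed `w` matrix must be
#' row-stochastic (the error names the offending row). A missing
#' `observed` field is tolerated (prediction-only workflows). A write
#' followed by a read recovers the cohort exactly.
#'
#' @param cohort Cohort tibble (see [generate_cohort()] for the columns).
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns the cohort tibble.
#' @examples
#' path <- tempfile(fileext = ".json")
#' write_cohort(generate_cohort(2, seed = 1), path)
#' read_cohort(path)
#' @export
write_cohort <- function(cohort, path) {
  check_cohort(cohort)
  groups <- purrr::map(seq_len(nrow(cohort)), function(g) {
    rec <- list(
      group_id = cohort$group_id[g],
      n = cohort$n[g],
      m = cohort$m[g],
      supply = cohort$supply[g],
      experiment_kind = cohort$experiment_kind[g],
      simplex = cohort$simplex[g],
      x0 = mat_to_rows(cohort$x0[[g]]),
      chips = mat_to_rows(cohort$chips[[g]])
    )
    if (!is.null(cohort$observed[[g]])) {
      rec$observed <- mat_to_rows(cohort$observed[[g]])
    }
    box <- if ("box" %in% names(cohort)) cohort$box[[g]] else NULL
    if (!is.null(box)) {
      rec$box <- list(lower = box$lower, upper = box$upper, supply = box$supply)
    }
    rec
  })
  doc <- list(
    schema_version = COHORT_SCHEMA_VERSION,
    experiment_kind = unique(cohort$experiment_kind)[1],
    groups = groups
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", null = "null")
  invisible(path)
}

scalar_or_na <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x[[1]])) NA_real_ else as.numeric(x[[1]])
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  allowed_top <- c("schema_version", "experiment_kind", "groups")
  unknown_top <- setdiff(names(doc), allowed_top)
  if (length(unknown_top) > 0) {
    abort(sprintf("unknown top-level field '%s' in cohort file.", unknown_top[1]),
          class = "fjalloc_schema_error")
  }
  if (is.null(doc$groups) || length(doc$groups) == 0) {
    abort("cohort file contains no groups.", class = "fjalloc_schema_error")
  }
  cohort <- purrr::map_dfr(doc$groups, function(g) {
    gid <- if (is.null(g$group_id)) "<unnamed>" else g$group_id
    unknown <- setdiff(names(g), allowed_group_fields)
    if (length(unknown) > 0) {
      abort(sprintf("unknown field '%s' in group '%s'.", unknown[1], gid),
            class = "fjalloc_schema_error")
    }
    for (req in c("group_id", "x0", "chips")) {
      if (is.null(g[[req]])) {
        abort(sprintf("group '%s' is missing required field '%s'.", gid, req),
              class = "fjalloc_schema_error")
      }
    }
    x0 <- rows_to_mat(g$x0)
    chips <- rows_to_mat(g$chips)
    supply <- scalar_or_na(g$supply)
    simplex <- if (is.null(g$simplex)) TRUE else isTRUE(g$simplex)
    n <- if (is.null(g$n)) nrow(x0) else g$n
    m <- if (is.null(g$m)) ncol(x0) else g$m
    if (nrow(x0) != n || ncol(x0) != m) {
      abort(sprintf("x0 of group '%s' is not %d x %d.", gid, n, m),
            class = "fjalloc_schema_error")
    }
    if (simplex) {
      rs <- rowSums(x0)
      bad <- which(abs(rs - supply) > 1e-6 | apply(x0 < -1e-9, 1, any))
      if (length(bad) > 0) {
        abort(sprintf(
          "row %d of x0 in group '%s' is not on the supply-%g simplex.",
          bad[1], gid, supply
        ), class = "fjalloc_schema_error")
      }
    }
    if (nrow(chips) != n || ncol(chips) != n) {
      abort(sprintf("chips of group '%s' is not %d x %d.", gid, n, n),
            class = "fjalloc_schema_error")
    }
    bad_chips <- which(rowSums(chips) <= 0 | apply(chips < 0, 1, any))
    if (length(bad_chips) > 0) {
      abort(sprintf("row %d of chips in group '%s' is unusable.",
                    bad_chips[1], gid),
            class = "fjalloc_schema_error")
    }
    if (!is.null(g$w)) {
      W <- rows_to_mat(g$w)
      bad_w <- which(abs(rowSums(W) - 1) > 1e-9)
      if (length(bad_w) > 0) {
        abort(sprintf(
          "row %d of W in group '%s' sums to %.6g, not 1.",
          bad_w[1], gid, rowSums(W)[bad_w[1]]
        ), class = "fjalloc_schema_error")
      }
    }
    observed <- rows_to_mat(g$observed)
    box <- if (!is.null(g$box)) {
      decision_polytope(
        lower = as.numeric(unlist(g$box$lower)),
        upper = as.numeric(unlist(g$box$upper)),
        supply = scalar_or_na(g$box$supply)
      )
    } else {
      NULL
    }
    new_group_record(
      group_id = gid, x0 = x0, chips = chips, supply = supply,
      simplex = simplex,
      experiment_kind = if (is.null(g$experiment_kind)) {
        if (is.null(doc$experiment_kind)) "unconstrained" else doc$experiment_kind
      } else {
        g$experiment_kind
      },
      observed = observed, box = box
    )
  })
  cohort
}

#' Flat CSV export of a cohort
#'
#' One row per member: group descriptors, the member's initial opinion,
#' chip allocation (columns padded with `NA` up to the largest group size),
#' and observed final if present. A flat export for spreadsheet use; the
#' JSON cohort file is the canonical lossless format.
#'
#' @param cohort Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  check_cohort(cohort)
  max_n <- max(cohort$n)
  rows <- purrr::map_dfr(seq_len(nrow(cohort)), function(g) {
    x0 <- cohort$x0[[g]]
    chips <- cohort$chips[[g]]
    obs <- cohort$observed[[g]]
    n <- cohort$n[g]
    m <- cohort$m[g]
    rec <- tibble::tibble(
      group_id = cohort$group_id[g],
      member = seq_len(n),
      n = n, m = m,
      supply = cohort$supply[g],
      experiment_kind = cohort$experiment_kind[g]
    )
    for (j in seq_len(m)) rec[[paste0("x0_", j)]] <- x0[, j]
    for (j in seq_len(max_n)) {
      rec[[paste0("chips_", j)]] <- if (j <= n) chips[, j] else NA_integer_
    }
    for (j in seq_len(m)) {
      rec[[paste0("observed_", j)]] <- if (is.null(obs)) NA_real_ else obs[, j]
    }
    rec
  })
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Export a prediction as JSON
#'
#' Writes an [fj_equilibrium()] result with keys `x_hat`, `v`, `changes`,
#' `method`, at full precision.
#'
#' @param prediction An `fj_prediction` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prediction <- function(prediction, path) {
  stopifnot(inherits(prediction, "fj_prediction"))
  jsonlite::write_json(
    list(
      x_hat = mat_to_rows(prediction$x_hat),
      v = mat_to_rows(prediction$v),
      changes = mat_to_rows(prediction$changes),
      method = prediction$method
    ),
    path, auto_unbox = TRUE, digits = I(17), null = "null"
  )
  invisible(path)
}
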