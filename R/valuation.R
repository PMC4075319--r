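# Contest-based vertex valuation and the visual encoding of values.
#
# Each head-to-head comparison is a "contest" seen from one regimen:
# outcome E in {-1, 0, +1} (lose / tie / win) weighted by the quality of the
# measured endpoint RV (1.0 weak surrogate, 1.25 strong surrogate such as
# PFS, 1.5 overall survival). A regimen's value is the mean of RV*E over its
# m contests, scaled by the logarithm of the total patients across those
# contests:
#
#   v = ( sum_y RV_y * E_y / m ) * log(N)
#
# Positive values classify the regimen superior (green), negative inferior
# (red), near-zero equivocal (yellow).

#' Valuation and display parameters
#'
#' @param log_base Base of the logarithm applied to the contest patient
#'   total. Only rescales all values uniformly; signs, ordering, and
#'   classifications are unaffected. Default 10.
#' @param epsilon Half-width of the "about zero" equivocal band on the value
#'   scale. Default 0: a pure sign rule.
#' @param rv Named numeric vector of relative-value weights for the three
#'   outcome classes.
#' @param anchors List of RGB triples (0-255) anchoring the diverging node
#'   color scale and the discrete edge scale: `inferior` red, `equivocal`
#'   yellow, `superior` green.
#' @param node_area Named numeric: display area per patient and min/max area
#'   clamps (display units squared). Node *area*, not radius, is proportional
#'   to the regimen's cumulative patient total.
#' @param edge_width Named numeric: stroke width per patient compared and
#'   min/max width clamps (display units).
#' @param decay Per-year alpha opacity decrement.
#' @param alpha_floor Minimum alpha opacity.
#' @return A list of class `evinet_params`.
#' @export
valuation_params <- function(log_base = 10,
                             epsilon = 0,
                             rv = c(weak = 1.0, strong = 1.25, os = 1.5),
                             anchors = list(inferior = c(255, 0, 0),
                                            equivocal = c(255, 255, 0),
                                            superior = c(0, 160, 0)),
                             node_area = c(per_patient = 2, min = 40, max = 4000),
                             edge_width = c(per_patient = 0.005, min = 0.5, max = 8),
                             decay = 0.1,
                             alpha_floor = 0.2) {
  stopifnot(log_base > 1, epsilon >= 0,
            all(c("weak", "strong", "os") %in% names(rv)),
            all(c("per_patient", "min", "max") %in% names(node_area)),
            all(c("per_patient", "min", "max") %in% names(edge_width)),
            decay > 0, alpha_floor > 0, alpha_floor <= 1)
  structure(list(log_base = log_base, epsilon = epsilon, rv = rv,
                 anchors = anchors, node_area = node_area,
                 edge_width = edge_width, decay = decay,
                 alpha_floor = alpha_floor),
            class = "evinet_params")
}

#' Contest outcome from one regimen's viewpoint
#'
#' @param annotation One comparison: a one-row data frame or list with
#'   `regimen_a`, `regimen_b`, `verdict` (`a`/`b`/`tie`).
#' @param viewpoint Canonical name of one of the two regimens.
#' @return `+1` if the viewpoint regimen won, `-1` if it lost, `0` for a tie.
#'   Antisymmetric: the two viewpoints' outcomes sum to zero.
#' @export
contest_outcome <- function(annotation, viewpoint) {
  a <- as.list(annotation)
  if (!viewpoint %in% c(a$regimen_a, a$regimen_b)) {
    rlang::abort(sprintf("viewpoint '%s' is not part of the comparison %s vs %s",
                         viewpoint, a$regimen_a, a$regimen_b))
  }
  if (a$verdict == "tie") return(0L)
  winner <- if (a$verdict == "a") a$regimen_a else a$regimen_b
  if (identical(viewpoint, winner)) 1L else -1L
}

#' Relative value of an outcome class
#'
#' @param outcome_class Character vector: `weak`, `strong`, or `os` (long
#'   forms accepted).
#' @param rv Named weight vector, by default 1.0 / 1.25 / 1.5.
#' @return Numeric weights.
#' @export
relative_value <- function(outcome_class, rv = c(weak = 1.0, strong = 1.25, os = 1.5)) {
  key <- map_token(outcome_class, .class_aliases, "outcome_class")
  unname(rv[key])
}

#' Vertex value from a list of contests
#'
#' Evaluates `v = mean(rv * E) * log(n_total, log_base)`, returning 0 for a
#' vertex with no contests or with a patient total of at most 1 (degenerate
#' logarithm): a regimen with no interpretable evidence is equivocal.
#'
#' @param contests Data frame with columns `E` (-1/0/+1), `rv`, and
#'   (unless `n_total` is given) `n_compared`, one row per contest.
#' @param n_total Total patients across all the vertex's contests; defaults
#'   to `sum(contests$n_compared)` with unknown (NA) counts contributing 0.
#' @param log_base Logarithm base (default 10).
#' @return A single numeric value.
#' @export
vertex_value <- function(contests, n_total = NULL, log_base = 10) {
  contests <- tibble::as_tibble(contests)
  m <- nrow(contests)
  if (is.null(n_total)) {
    n_total <- sum(dplyr::coalesce(as.numeric(contests$n_compared), 0))
  }
  if (m == 0L || n_total <= 1) return(0)
  mean(contests$rv * contests$E) * log(n_total, base = log_base)
}

#' Classify a vertex value
#'
#' @param v Numeric vector of vertex values.
#' @param epsilon Equivocal half-band; with `epsilon = 0` the rule is pure
#'   sign (equivocal iff exactly zero).
#' @return Character vector: `"superior"`, `"equivocal"`, or `"inferior"`.
#' @export
classify_vertex <- function(v, epsilon = 0) {
  stopifnot(epsilon >= 0)
  dplyr::case_when(v > epsilon ~ "superior",
                   v < -epsilon ~ "inferior",
                   TRUE ~ "equivocal")
}

rgb_hex <- function(m) {
  grDevices::rgb(m[, 1], m[, 2], m[, 3], maxColorValue = 255)
}

#' Diverging node color for a vertex value
#'
#' Piecewise-linear interpolation on the symmetric domain
#' `[-v_max, +v_max]`: `-v_max` maps to the inferior anchor (red), 0 to the
#' equivocal anchor (yellow), `+v_max` to the superior anchor (green);
#' values outside the domain are clamped. Channel-wise monotone in `v`.
#'
#' @param v Numeric vector of vertex values.
#' @param v_max Positive scale: the snapshot-wide maximum absolute value
#'   (use 1 when all values are zero).
#' @param anchors Anchor RGB triples, see [valuation_params()].
#' @return Character vector of `#RRGGBB` hex colors.
#' @export
value_to_color <- function(v, v_max,
                           anchors = valuation_params()$anchors) {
  stopifnot(v_max > 0)
  t <- pmin(1, pmax(-1, v / v_max))
  lo <- do.call(rbind, lapply(t, function(ti) {
    if (ti < 0) {
      w <- -ti
      round((1 - w) * anchors$equivocal + w * anchors$inferior)
    } else {
      w <- ti
      round((1 - w) * anchors$equivocal + w * anchors$superior)
    }
  }))
  rgb_hex(lo)
}

#' Discrete edge color for an outcome class
#'
#' Edges are colored by evidence quality without gradation, reusing the node
#' scale anchors: weak surrogate red, strong surrogate yellow, overall
#' survival green.
#'
#' @inheritParams relative_value
#' @param anchors Anchor RGB triples.
#' @return Character vector of hex colors.
#' @export
edge_color <- function(outcome_class,
                       anchors = valuation_params()$anchors) {
  key <- map_token(outcome_class, .class_aliases, "outcome_class")
  pal <- c(weak = rgb_hex(matrix(anchors$inferior, 1)),
           strong = rgb_hex(matrix(anchors$equivocal, 1)),
           os = rgb_hex(matrix(anchors$superior, 1)))
  unname(pal[key])
}

#' Node display area for a patient total
#'
#' Area (not radius) is linear in the cumulative number of patients who
#' received the regimen, clamped to `[min, max]`; zero patients map to the
#' minimum area.
#'
#' @param total_patients Non-negative numeric vector.
#' @param node_area Named numeric `per_patient`, `min`, `max`.
#' @return Numeric vector of areas in display units squared.
#' @export
node_display_size <- function(total_patients,
                              node_area = valuation_params()$node_area) {
  stopifnot(all(total_patients >= 0))
  pmin(node_area[["max"]],
       pmax(node_area[["min"]], node_area[["per_patient"]] * total_patients))
}

#' Edge display width for a compared patient count
#'
#' Width is linear in the number of patients compared by the edge's own
#' trial, clamped to `[min, max]`; each duplicate (parallel) edge is sized
#' independently from its own trial.
#'
#' @param n_compared Non-negative numeric vector (0 when unknown).
#' @param edge_width Named numeric `per_patient`, `min`, `max`.
#' @return Numeric vector of stroke widths.
#' @export
edge_display_width <- function(n_compared,
                               edge_width = valuation_params()$edge_width) {
  stopifnot(all(n_compared >= 0))
  pmin(edge_width[["max"]],
       pmax(edge_width[["min"]], edge_width[["per_patient"]] * n_compared))
}

#' Contests seen by each vertex of a registry up to a year
#'
#' Expands the comparison rows into per-vertex contests: each annotation
#' contributes one contest to each endpoint, so an arm of a k-arm trial
#' receives k-1 contests.
#'
#' @param registry A `trial_registry`.
#' @param as_of_year Include trials published in or before this year.
#' @param params An [valuation_params()] list.
#' @return Tibble with columns `regimen`, `trial_id`, `year`, `E`, `rv`,
#'   `n_compared`.
#' @export
vertex_contests <- function(registry, as_of_year = max(registry$year),
                            params = valuation_params()) {
  rows <- registry[registry$year <= as_of_year, ]
  n_cmp <- dplyr::coalesce(as.numeric(rows$n_a), 0) +
    dplyr::coalesce(as.numeric(rows$n_b), 0)
  rv <- unname(params$rv[rows$outcome_class])
  e_a <- dplyr::case_when(rows$verdict == "a" ~ 1, rows$verdict == "b" ~ -1,
                          TRUE ~ 0)
  dplyr::bind_rows(
    tibble::tibble(regimen = rows$regimen_a, trial_id = rows$trial_id,
                   year = rows$year, E = e_a, rv = rv, n_compared = n_cmp),
    tibble::tibble(regimen = rows$regimen_b, trial_id = rows$trial_id,
                   year = rows$year, E = -e_a, rv = rv, n_compared = n_cmp)
  ) |>
    dplyr::arrange(.data$regimen, .data$year, .data$trial_id)
}

#' Per-vertex values for a registry snapshot
#'
#' @inheritParams vertex_contests
#' @return Tibble with one row per regimen appearing by `as_of_year`:
#'   `regimen`, `m` (number of contests), `n_total` (patients across its
#'   contests), `total_patients` (patients on its own arms, sizes the node),
#'   `value`, `classification`.
#' @export
vertex_values <- function(registry, as_of_year = max(registry$year),
                          params = valuation_params()) {
  contests <- vertex_contests(registry, as_of_year, params)
  arms <- trial_arms(registry[registry$year <= as_of_year, ])
  own <- arms |>
    dplyr::group_by(.data$regimen) |>
    dplyr::summarise(total_patients = sum(.data$n, na.rm = TRUE),
                     .groups = "drop")
  contests |>
    dplyr::group_by(.data$regimen) |>
    dplyr::summarise(m = dplyr::n(), n_total = sum(.data$n_compared),
                     value = vertex_value(dplyr::pick(dplyr::everything()),
                                          log_base = params$log_base),
                     .groups = "drop") |>
    dplyr::left_join(own, by = "regimen") |>
    dplyr::mutate(
      total_patients = dplyr::coalesce(.data$total_patients, 0L),
      classification = classify_vertex(.data$value, params$epsilon)
    ) |>
    dplyr::arrange(.data$regimen)
}
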