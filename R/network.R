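# Evidence network snapshots: the regimen multigraph as of a given year,
# plus its structural statistics and graph-file export.

#' Build the evidence network as of a year
#'
#' Vertices are all regimens appearing in trials published up to
#' `as_of_year`; each (trial, unordered arm pair) contributes its own edge,
#' so repeat comparisons of the same pair are parallel edges. The snapshot
#' carries the full valuation, classification, alpha opacity (evolved year
#' by year from the first trial, with decay, refresh, and cascade refresh),
#' and display attributes.
#'
#' @param registry A `trial_registry`.
#' @param as_of_year Integer year; must not precede the earliest trial.
#' @param params An [valuation_params()] list.
#' @return An `evinet_network` object with tibbles `$vertices` and `$edges`.
#' @export
build_network <- function(registry, as_of_year = max(registry$year),
                          params = valuation_params()) {
  first <- min(registry$year)
  if (as_of_year < first) {
    rlang::abort(sprintf(
      "as_of_year %d precedes the earliest trial (%d): no evidence yet",
      as_of_year, first))
  }
  net <- empty_network(first - 1L, params)
  for (y in seq.int(first, as_of_year)) {
    net <- advance_year(net, registry[registry$year == y, ])
  }
  net
}

empty_network <- function(year, params = valuation_params()) {
  structure(list(
    as_of_year = as.integer(year),
    vertices = tibble::tibble(regimen = character(), m = integer(),
                              n_total = numeric(), total_patients = numeric(),
                              value = numeric(), classification = character(),
                              alpha = numeric(), area = numeric(),
                              color = character()),
    edges = tibble::tibble(trial_id = character(), regimen_a = character(),
                           regimen_b = character(), year = integer(),
                           outcome_class = character(), verdict = character(),
                           basis = character(), n_compared = numeric(),
                           alpha = numeric(), width = numeric(),
                           color = character()),
    records = NULL,
    params = params
  ), class = "evinet_network")
}

#' Multigraph degree of a regimen
#'
#' Counts incident edges including parallel duplicates.
#'
#' @param network An `evinet_network`.
#' @param regimen Canonical regimen name(s); default all vertices.
#' @return Tibble with columns `regimen`, `degree`.
#' @export
regimen_degree <- function(network, regimen = NULL) {
  e <- network$edges
  counts <- table(c(e$regimen_a, e$regimen_b))
  out <- tibble::tibble(
    regimen = network$vertices$regimen,
    degree = as.integer(dplyr::coalesce(
      as.integer(counts[network$vertices$regimen]), 0L))
  )
  if (!is.null(regimen)) {
    unknown <- setdiff(regimen, out$regimen)
    if (length(unknown)) {
      rlang::abort(sprintf("unknown regimen(s): %s",
                           paste(unknown, collapse = ", ")))
    }
    out <- out[match(regimen, out$regimen), ]
  }
  out
}

#' Singly connected regimens
#'
#' Vertices with exactly one incident edge in the multigraph. A vertex with
#' one neighbour reached by two parallel edges is *not* singly connected.
#'
#' @param network An `evinet_network`.
#' @return Character vector of canonical regimen names.
#' @export
singly_connected <- function(network) {
  d <- regimen_degree(network)
  sort(d$regimen[d$degree == 1L])
}

#' Cumulative patients who received a regimen
#'
#' Sums the enrollment over all of the regimen's trial arms up to
#' `as_of_year`; unknown enrollments contribute 0 and are flagged.
#'
#' @param registry A `trial_registry`.
#' @param regimen Canonical regimen name.
#' @param as_of_year Integer year.
#' @return Integer total, with attribute `n_unknown` counting arms whose
#'   enrollment was not reported.
#' @export
vertex_patient_total <- function(registry, regimen,
                                 as_of_year = max(registry$year)) {
  arms <- trial_arms(registry[registry$year <= as_of_year, ])
  arms <- arms[arms$regimen == regimen, ]
  structure(sum(arms$n, na.rm = TRUE), n_unknown = sum(is.na(arms$n)))
}

#' Yearly cumulative summary statistics
#'
#' For each year of `year_range`: the number of distinct regimens, trials,
#' and patients accrued so far, plus the patient series rescaled to equal
#' 100 in the final year.
#'
#' @param registry A `trial_registry`.
#' @param year_range Integer vector of years (default first through last
#'   trial year).
#' @return Tibble `year`, `regimens`, `trials`, `patients`,
#'   `patients_normalized`.
#' @export
summary_stats <- function(registry,
                          year_range = seq.int(min(registry$year),
                                               max(registry$year))) {
  stopifnot(length(year_range) > 0)
  arms <- trial_arms(registry)
  out <- purrr::map_dfr(sort(unique(as.integer(year_range))), function(y) {
    a <- arms[arms$year <= y, ]
    tibble::tibble(year = y,
                   regimens = dplyr::n_distinct(a$regimen),
                   trials = dplyr::n_distinct(a$trial_id),
                   patients = sum(a$n, na.rm = TRUE))
  })
  final <- out$patients[nrow(out)]
  out$patients_normalized <- if (final > 0) 100 * out$patients / final else
    rep(NA_real_, nrow(out))
  out
}

#' Convert a snapshot to an igraph multigraph
#'
#' Vertex and edge display attributes (value, alpha, classification, color,
#' patient totals) travel as igraph attributes; parallel edges are kept.
#'
#' @param x An `evinet_network`.
#' @param ... Unused.
#' @return An `igraph` object.
#' @export
#' @method as.igraph evinet_network
as.igraph.evinet_network <- function(x, ...) {
  v <- x$vertices
  e <- x$edges
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = e$regimen_a, to = e$regimen_b,
                   trial_id = e$trial_id, year = e$year,
                   outcome_class = e$outcome_class,
                   n_compared = e$n_compared, alpha = e$alpha,
                   width = e$width, color = e$color,
                   stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = v$regimen, canonical_name = v$regimen,
                          value = v$value, alpha = v$alpha,
                          classification = v$classification,
                          total_patients = v$total_patients,
                          area = v$area, color = v$color,
                          stringsAsFactors = FALSE)
  )
  igraph::graph_attr(g, "as_of_year") <- x$as_of_year
  g
}

#' Export a snapshot to GraphML or GML
#'
#' @param network An `evinet_network`.
#' @param path Output path.
#' @param format `"graphml"` (multigraph dialect, default) or `"gml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("graphml", "gml")) {
  format <- match.arg(format)
  igraph::write_graph(as.igraph(network), path, format = format)
  invisible(path)
}

#' @export
print.evinet_network <- function(x, ...) {
  cat(sprintf("<evinet_network> as of %d: %d regimens, %d edges (%d trials)\n",
              x$as_of_year, nrow(x$vertices), nrow(x$edges),
              dplyr::n_distinct(x$edges$trial_id)))
  invisible(x)
}
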