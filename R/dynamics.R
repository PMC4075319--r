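# Temporal dynamics: year-by-year evolution of the evidence network under
# the recency (alpha opacity) model — decay, refresh on new evidence, and
# cascade refresh when a regimen's classification flips between superior
# and inferior.

# Alphas live on the 0.1 grid; snap tiny floating-point residue after each
# decrement so iterated decay and the closed form agree exactly.
snap_alpha <- function(a) round(a, 10)

#' One year of alpha decay
#'
#' @param alpha_prev Numeric vector of alphas in `[floor, 1]`.
#' @param decay Per-year decrement (default 0.1).
#' @param floor Minimum alpha (default 0.2).
#' @return `max(floor, alpha_prev - decay)`, elementwise.
#' @export
decay_alpha <- function(alpha_prev, decay = 0.1, floor = 0.2) {
  if (any(alpha_prev < floor - 1e-9 | alpha_prev > 1 + 1e-9)) {
    rlang::abort(sprintf("alpha out of range [%s, 1]", format(floor)))
  }
  pmax(floor, snap_alpha(alpha_prev - decay))
}

#' Closed-form alpha after a number of years without refresh
#'
#' @param years_since_refresh Non-negative integer vector.
#' @inheritParams decay_alpha
#' @return `max(floor, 1 - decay * years)`, elementwise; agrees exactly with
#'   iterating [decay_alpha()].
#' @export
alpha_after <- function(years_since_refresh, decay = 0.1, floor = 0.2) {
  stopifnot(all(years_since_refresh >= 0))
  pmax(floor, snap_alpha(1 - decay * years_since_refresh))
}

#' Advance a snapshot by one year
#'
#' Applies, in order: (1) decay every existing node and edge alpha;
#' (2) insert the year's new vertices and edges with alpha 1.0; (3) refresh
#' to alpha 1.0 every existing node involved in a new trial; (4) recompute
#' all vertex values and classifications from the cumulative evidence;
#' (5) cascade: refresh to 1.0 all vertices adjacent to any vertex whose
#' classification flipped between superior and inferior; (6) recompute
#' display attributes (node areas, colors on the snapshot-wide value scale;
#' edge widths and colors). Edges never refresh — their alpha reflects only
#' their own trial's age.
#'
#' @param prev An `evinet_network` for year y.
#' @param new_trials A `trial_registry` slice containing only trials
#'   published in year y+1 (may be empty).
#' @return The `evinet_network` for year y+1.
#' @export
advance_year <- function(prev, new_trials) {
  params <- prev$params
  year <- prev$as_of_year + 1L
  new_trials <- tibble::as_tibble(new_trials)
  if (nrow(new_trials) && any(new_trials$year != year)) {
    rlang::abort(sprintf("advance_year to %d received trials from other years",
                         year))
  }

  # (1) decay
  v <- prev$vertices
  e <- prev$edges
  v$alpha <- decay_alpha(v$alpha, params$decay, params$alpha_floor)
  if (nrow(e)) e$alpha <- decay_alpha(e$alpha, params$decay, params$alpha_floor)

  records <- dplyr::bind_rows(prev$records, new_trials)

  # (2) insert new edges / vertices at alpha 1.0
  if (nrow(new_trials)) {
    keys <- pair_sorted(new_trials$regimen_a, new_trials$regimen_b)
    new_e <- tibble::tibble(
      trial_id = new_trials$trial_id,
      regimen_a = keys$lo, regimen_b = keys$hi,
      year = new_trials$year,
      outcome_class = new_trials$outcome_class,
      verdict = new_trials$verdict, basis = new_trials$basis,
      n_compared = dplyr::coalesce(as.numeric(new_trials$n_a), 0) +
        dplyr::coalesce(as.numeric(new_trials$n_b), 0),
      alpha = 1.0, width = NA_real_, color = NA_character_
    )
    e <- dplyr::bind_rows(e, new_e)
    touched <- unique(c(new_trials$regimen_a, new_trials$regimen_b))
    fresh <- setdiff(touched, v$regimen)
    if (length(fresh)) {
      v <- dplyr::bind_rows(v, tibble::tibble(
        regimen = fresh, m = 0L, n_total = 0, total_patients = 0,
        value = 0, classification = "equivocal", alpha = 1.0,
        area = NA_real_, color = NA_character_))
    }
    # (3) refresh nodes involved in a new trial
    v$alpha[v$regimen %in% touched] <- 1.0
  }

  # (4) revalue on cumulative evidence
  vals <- vertex_values(records, as_of_year = year, params = params)
  vals <- vals[order(vals$regimen, method = "radix"), ]
  v <- v[order(v$regimen, method = "radix"), ]
  stopifnot(identical(vals$regimen, v$regimen))
  old_class <- v$classification
  v$m <- vals$m
  v$n_total <- vals$n_total
  v$total_patients <- as.numeric(vals$total_patients)
  v$value <- vals$value
  v$classification <- vals$classification

  # (5) cascade refresh on superior <-> inferior flips of pre-existing nodes
  pre_existing <- v$regimen %in% prev$vertices$regimen
  flipped <- pre_existing &
    ((old_class == "superior" & v$classification == "inferior") |
       (old_class == "inferior" & v$classification == "superior"))
  if (any(flipped)) {
    for (r in v$regimen[flipped]) {
      nbr <- unique(c(e$regimen_b[e$regimen_a == r],
                      e$regimen_a[e$regimen_b == r]))
      v$alpha[v$regimen %in% nbr] <- 1.0
    }
  }

  # (6) display attributes
  v_max <- max(abs(v$value), 0)
  if (v_max == 0) v_max <- 1
  v$area <- node_display_size(v$total_patients, params$node_area)
  v$color <- value_to_color(v$value, v_max, params$anchors)
  if (nrow(e)) {
    e$width <- edge_display_width(e$n_compared, params$edge_width)
    e$color <- edge_color(e$outcome_class, params$anchors)
    e <- e[order(e$year, e$trial_id, e$regimen_a, e$regimen_b,
                 method = "radix"), ]
  }

  structure(list(as_of_year = year, vertices = v, edges = e,
                 records = records, params = params),
            class = "evinet_network")
}

#' Build the full yearly timeline
#'
#' One snapshot per calendar year from the earliest to the latest trial
#' year, each produced from its predecessor by [advance_year()].
#' Deterministic given the registry.
#'
#' @param registry A non-empty `trial_registry`.
#' @param params An [valuation_params()] list.
#' @return An `evinet_timeline`: list with `$snapshots` (named by year),
#'   `$first_year`, `$last_year`.
#' @export
build_timeline <- function(registry, params = valuation_params()) {
  if (!nrow(registry)) rlang::abort("empty registry: no trials to place in time")
  first <- min(registry$year)
  last <- max(registry$year)
  snaps <- vector("list", last - first + 1L)
  net <- empty_network(first - 1L, params)
  for (y in seq.int(first, last)) {
    net <- advance_year(net, registry[registry$year == y, ])
    snaps[[y - first + 1L]] <- net
  }
  names(snaps) <- as.character(seq.int(first, last))
  structure(list(snapshots = snaps, first_year = first, last_year = last,
                 params = params),
            class = "evinet_timeline")
}

#' Extract one snapshot from a timeline
#'
#' @param timeline An `evinet_timeline`.
#' @param year Integer year within the timeline span.
#' @return An `evinet_network`.
#' @export
network_at <- function(timeline, year) {
  key <- as.character(as.integer(year))
  if (!key %in% names(timeline$snapshots)) {
    rlang::abort(sprintf("year %s outside the timeline span %d-%d", key,
                         timeline$first_year, timeline$last_year))
  }
  timeline$snapshots[[key]]
}

#' Classification flip events along a timeline
#'
#' Lists every transition of a vertex between the superior and inferior
#' classes across consecutive yearly snapshots (transitions into or out of
#' equivocal are not flips).
#'
#' @param timeline An `evinet_timeline`.
#' @return Tibble `year`, `regimen`, `old_class`, `new_class`, in
#'   chronological order.
#' @export
flip_events <- function(timeline) {
  yrs <- seq.int(timeline$first_year, timeline$last_year)
  out <- purrr::map_dfr(yrs[-1], function(y) {
    prev <- network_at(timeline, y - 1L)$vertices
    cur <- network_at(timeline, y)$vertices
    joined <- dplyr::inner_join(
      prev[c("regimen", "classification")],
      cur[c("regimen", "classification")],
      by = "regimen", suffix = c("_old", "_new"))
    hit <- (joined$classification_old == "superior" &
              joined$classification_new == "inferior") |
      (joined$classification_old == "inferior" &
         joined$classification_new == "superior")
    tibble::tibble(year = y, regimen = joined$regimen[hit],
                   old_class = joined$classification_old[hit],
                   new_class = joined$classification_new[hit])
  })
  if (!nrow(out)) {
    out <- tibble::tibble(year = integer(), regimen = character(),
                          old_class = character(), new_class = character())
  }
  out
}

#' Export a timeline: one GraphML per year plus a flip-events CSV
#'
#' @param timeline An `evinet_timeline`.
#' @param dir Output directory (created if needed).
#' @return Tibble of written files, invisibly.
#' @export
write_timeline <- function(timeline, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- purrr::map_chr(names(timeline$snapshots), function(y) {
    path <- file.path(dir, sprintf("network_%s.graphml", y))
    write_network(timeline$snapshots[[y]], path, format = "graphml")
    path
  })
  flips_path <- file.path(dir, "flip_events.csv")
  readr::write_csv(flip_events(timeline), flips_path)
  invisible(tibble::tibble(file = c(files, flips_path)))
}

#' @export
print.evinet_timeline <- function(x, ...) {
  fl <- flip_events(x)
  cat(sprintf("<evinet_timeline> %d-%d (%d yearly snapshots), %d flip event(s)\n",
              x$first_year, x$last_year, length(x$snapshots), nrow(fl)))
  invisible(x)
}
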