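# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom igraph as.igraph
#' @export
igraph::as.igraph

#' Tidy an evidence network snapshot
#'
#' @param x An `evinet_network`.
#' @param what `"vertices"` (default) or `"edges"`.
#' @param ... Unused.
#' @return A tibble of per-vertex or per-edge states.
#' @method tidy evinet_network
#' @export
tidy.evinet_network <- function(x, what = c("vertices", "edges"), ...) {
  what <- match.arg(what)
  out <- x[[what]]
  out$as_of_year <- x$as_of_year
  dplyr::relocate(out, "as_of_year")
}

#' One-row summary of a snapshot
#'
#' @param x An `evinet_network`.
#' @param ... Unused.
#' @return Tibble with vertex/edge/trial counts, patient totals, degree
#'   extremes, and the number of singly connected regimens.
#' @method glance evinet_network
#' @export
glance.evinet_network <- function(x, ...) {
  d <- regimen_degree(x)
  tibble::tibble(
    as_of_year = x$as_of_year,
    n_vertices = nrow(x$vertices),
    n_edges = nrow(x$edges),
    n_trials = dplyr::n_distinct(x$edges$trial_id),
    total_patients = sum(x$vertices$total_patients),
    max_degree = if (nrow(d)) max(d$degree) else 0L,
    n_singly_connected = length(singly_connected(x))
  )
}

#' Tidy a timeline into a long per-year vertex table
#'
#' @param x An `evinet_timeline`.
#' @param ... Unused.
#' @return Tibble of vertex states stacked over the yearly snapshots.
#' @method tidy evinet_timeline
#' @export
tidy.evinet_timeline <- function(x, ...) {
  purrr::map_dfr(x$snapshots, tidy, what = "vertices")
}

#' One-row summary of a timeline
#'
#' @param x An `evinet_timeline`.
#' @param ... Unused.
#' @return Tibble with the span, snapshot count, final-year size, and the
#'   number of superior/inferior flip events.
#' @method glance evinet_timeline
#' @export
glance.evinet_timeline <- function(x, ...) {
  final <- network_at(x, x$last_year)
  tibble::tibble(
    first_year = x$first_year, last_year = x$last_year,
    n_snapshots = length(x$snapshots),
    n_vertices_final = nrow(final$vertices),
    n_edges_final = nrow(final$edges),
    n_flips = nrow(flip_events(x))
  )
}

#' @rdname quality_recovery_report
#' @param x A `quality_recovery` object.
#' @param ... Unused.
#' @method tidy quality_recovery
#' @export
tidy.quality_recovery <- function(x, ...) x$regimens

#' @rdname quality_recovery_report
#' @method glance quality_recovery
#' @export
glance.quality_recovery <- function(x, ...) {
  tibble::tibble(spearman = x$spearman, kendall = x$kendall,
                 n_decisive = x$n_decisive,
                 n_regimens = nrow(x$regimens))
}

#' Plot a snapshot with ggplot2
#'
#' A quick diagnostic view of the full visual grammar (the SVG/PNG renderer
#' is the publication path): nodes colored by value, sized by patients,
#' faded by alpha; edges colored by outcome class with parallel-edge
#' curvature.
#'
#' @param object An `evinet_network`.
#' @param layout An `evinet_layout` (default computed with `seed`).
#' @param seed Layout seed used when `layout` is `NULL`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot evinet_network
#' @export
autoplot.evinet_network <- function(object, layout = NULL, seed = 1L, ...) {
  if (is.null(layout)) layout <- layout_network(object, seed = seed)
  v <- dplyr::left_join(object$vertices, layout, by = "regimen")
  e <- object$edges
  p <- ggplot2::ggplot()
  if (nrow(e)) {
    key <- paste(e$regimen_a, e$regimen_b, sep = "\r")
    curv <- stats::ave(seq_along(key), key, FUN = function(i) {
      k <- length(i)
      (seq_len(k) - (k + 1) / 2) * 0.25
    })
    ia <- match(e$regimen_a, layout$regimen)
    ib <- match(e$regimen_b, layout$regimen)
    ed <- tibble::tibble(x = layout$x[ia], y = layout$y[ia],
                         xend = layout$x[ib], yend = layout$y[ib],
                         color = e$color, alpha = e$alpha,
                         width = e$width, curv = curv)
    for (cv in unique(ed$curv)) {
      sub <- ed[ed$curv == cv, ]
      p <- p + ggplot2::geom_curve(
        data = sub, curvature = cv,
        ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                     yend = .data$yend, colour = .data$color,
                     alpha = .data$alpha, linewidth = .data$width))
    }
  }
  p +
    ggplot2::geom_point(
      data = v,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$color,
                   alpha = .data$alpha, size = .data$area),
      shape = 21, colour = "grey20") +
    ggplot2::geom_text(
      data = v,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$regimen,
                   alpha = .data$alpha),
      size = 3, vjust = -1.2) +
    ggplot2::scale_colour_identity() +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_alpha_identity() +
    ggplot2::scale_size_area(max_size = 18, guide = "none") +
    ggplot2::scale_linewidth_identity() +
    ggplot2::labs(title = sprintf("Evidence network, %d", object$as_of_year)) +
    ggplot2::theme_void()
}

#' Plot yearly cumulative summary statistics
#'
#' Regimen, trial, and patient accrual over time (log vertical scale), the
#' patient series normalized to 100 at the final year.
#'
#' @param object A `trial_registry`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trial_registry
#' @export
autoplot.trial_registry <- function(object, ...) {
  stats_tbl <- summary_stats(object) |>
    tidyr::pivot_longer(c("regimens", "trials", "patients_normalized"),
                        names_to = "series", values_to = "count")
  ggplot2::ggplot(stats_tbl,
                  ggplot2::aes(x = .data$year, y = .data$count,
                               colour = .data$series)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Year", y = "Cumulative count (log scale)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
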