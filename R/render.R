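# Layout and drawing: Kamada-Kawai placement warm-started across years, and
# snapshot rendering with the full visual grammar (value colors, patient
# sizes, alpha opacities, parallel-edge arcs, fading legend).

#' Kamada-Kawai layout for a snapshot
#'
#' Deterministic for a fixed (network, seed, prev). When `prev` is supplied,
#' its coordinates initialize the optimization so consecutive yearly layouts
#' stay visually stable; vertices new this year start near the centroid of
#' the warm-start positions with a small seeded jitter.
#'
#' @param network A non-empty `evinet_network`.
#' @param seed Integer seed for the placement.
#' @param prev Optional previous `evinet_layout` to warm-start from.
#' @return An `evinet_layout` tibble (`regimen`, `x`, `y`) with attributes
#'   `seed` and `warm_started`.
#' @export
layout_network <- function(network, seed = 1L, prev = NULL) {
  v <- network$vertices
  if (!nrow(v)) rlang::abort("cannot lay out an empty network")
  coords <- withr::with_seed(as.integer(seed), {
    if (nrow(v) == 1L) {
      matrix(0, nrow = 1, ncol = 2)
    } else {
      g <- as.igraph(network)
      init <- NULL
      if (!is.null(prev)) {
        init <- matrix(stats::runif(2L * nrow(v), -0.1, 0.1), ncol = 2)
        hit <- match(v$regimen, prev$regimen)
        centroid <- c(mean(prev$x), mean(prev$y))
        init <- sweep(init, 2, centroid, "+")
        init[!is.na(hit), 1] <- prev$x[hit[!is.na(hit)]]
        init[!is.na(hit), 2] <- prev$y[hit[!is.na(hit)]]
      }
      igraph::layout_with_kk(g, coords = init, maxiter = 500L)
    }
  })
  out <- tibble::tibble(regimen = v$regimen, x = coords[, 1], y = coords[, 2])
  # guarantee pairwise-distinct positions (degenerate optima only)
  dup <- duplicated(round(out[c("x", "y")], 9))
  if (any(dup)) {
    nudge <- withr::with_seed(as.integer(seed) + 1L,
                              stats::runif(sum(dup), 1e-4, 1e-3))
    out$x[dup] <- out$x[dup] + nudge
  }
  structure(out, seed = as.integer(seed), warm_started = !is.null(prev),
            class = c("evinet_layout", class(out)))
}

#' Rendering options
#'
#' @param width,height Canvas size in display units (px).
#' @param margin Margin around the drawing area, px.
#' @param labels Draw regimen names beside nodes.
#' @param legend Draw the regimen legend (entries fade with node alpha, so
#'   outdated regimens appear faint).
#' @param caption Extra caption text (the year is always shown).
#' @param bbox Optional fixed data-space bounding box
#'   `c(xmin, xmax, ymin, ymax)` so a frame sequence shares one canvas.
#' @param format `"svg"` or `"png"` (used by [render_frames()]).
#' @return A list of class `evinet_render_options`.
#' @export
render_options <- function(width = 900, height = 700, margin = 70,
                           labels = TRUE, legend = TRUE, caption = NULL,
                           bbox = NULL, format = c("svg", "png")) {
  structure(list(width = width, height = height, margin = margin,
                 labels = labels, legend = legend, caption = caption,
                 bbox = bbox, format = match.arg(format)),
            class = "evinet_render_options")
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

fmt_num <- function(x) formatC(x, format = "fg", digits = 6)

# scale data coordinates to the canvas
scale_coords <- function(layout, opts) {
  bb <- opts$bbox
  if (is.null(bb)) bb <- c(range(layout$x), range(layout$y))
  span_x <- max(bb[2] - bb[1], 1e-9)
  span_y <- max(bb[4] - bb[3], 1e-9)
  inner_w <- opts$width - 2 * opts$margin
  inner_h <- opts$height - 2 * opts$margin
  tibble::tibble(
    regimen = layout$regimen,
    px = opts$margin + (layout$x - bb[1]) / span_x * inner_w,
    py = opts$margin + (bb[4] - layout$y) / span_y * inner_h
  )
}

# per-edge perpendicular arc offsets: parallel edges between the same pair
# fan out symmetrically around the straight chord
edge_offsets <- function(edges) {
  key <- paste(edges$regimen_a, edges$regimen_b, sep = "\r")
  stats::ave(seq_along(key), key, FUN = function(i) {
    k <- length(i)
    (seq_len(k) - (k + 1) / 2) * 22
  })
}

svg_edge_path <- function(x1, y1, x2, y2, offset) {
  if (abs(offset) < 1e-9) {
    sprintf("M %s %s L %s %s", fmt_num(x1), fmt_num(y1), fmt_num(x2), fmt_num(y2))
  } else {
    mx <- (x1 + x2) / 2; my <- (y1 + y2) / 2
    len <- max(sqrt((x2 - x1)^2 + (y2 - y1)^2), 1e-9)
    nx <- -(y2 - y1) / len; ny <- (x2 - x1) / len
    sprintf("M %s %s Q %s %s %s %s", fmt_num(x1), fmt_num(y1),
            fmt_num(mx + offset * nx), fmt_num(my + offset * ny),
            fmt_num(x2), fmt_num(y2))
  }
}

#' Render one snapshot to SVG or PNG
#'
#' Node fill is the diverging value color at the node's alpha opacity; node
#' area is proportional to its cumulative patients; edge strokes carry the
#' outcome-class color, the trial-age alpha, and a width proportional to the
#' patients compared, with parallel edges drawn as offset arcs. The legend
#' repeats each regimen at its node alpha, so outdated regimens are faint.
#' Rendering is read-only: the network object is never modified.
#'
#' @param network An `evinet_network`.
#' @param layout An `evinet_layout` covering the network (default: computed
#'   with seed 1).
#' @param path Output file; extension `.svg` or `.png` selects the format.
#' @param options An [render_options()] list.
#' @return `path`, invisibly.
#' @export
render_snapshot <- function(network, layout = layout_network(network),
                            path, options = render_options()) {
  v <- network$vertices
  missing_v <- setdiff(v$regimen, layout$regimen)
  if (length(missing_v)) {
    rlang::abort(sprintf("layout lacks coordinates for: %s",
                         paste(missing_v, collapse = ", ")))
  }
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    render_png(network, layout, path, options)
  } else {
    render_svg(network, layout, path, options)
  }
  invisible(path)
}

render_svg <- function(network, layout, path, opts) {
  v <- network$vertices
  e <- network$edges
  pos <- scale_coords(layout, opts)
  vi <- match(v$regimen, pos$regimen)

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            round(opts$width), round(opts$height), round(opts$width),
            round(opts$height)),
    sprintf('<rect width="%d" height="%d" fill="white"/>',
            round(opts$width), round(opts$height))
  )

  if (nrow(e)) {
    offs <- edge_offsets(e)
    ia <- match(e$regimen_a, pos$regimen)
    ib <- match(e$regimen_b, pos$regimen)
    lines <- c(lines, '<g id="edges">', vapply(seq_len(nrow(e)), function(i) {
      sprintf('<path class="edge" data-trial="%s" d="%s" fill="none" stroke="%s" stroke-opacity="%s" stroke-width="%s"/>',
              xml_escape(e$trial_id[i]),
              svg_edge_path(pos$px[ia[i]], pos$py[ia[i]],
                            pos$px[ib[i]], pos$py[ib[i]], offs[i]),
              e$color[i], format(e$alpha[i]), fmt_num(e$width[i]))
    }, character(1)), '</g>')
  }

  radii <- sqrt(v$area / pi)
  lines <- c(lines, '<g id="nodes">', vapply(seq_len(nrow(v)), function(i) {
    sprintf('<circle class="node" data-regimen="%s" cx="%s" cy="%s" r="%s" fill="%s" fill-opacity="%s" stroke="#333333" stroke-width="0.7"/>',
            xml_escape(v$regimen[i]), fmt_num(pos$px[vi[i]]),
            fmt_num(pos$py[vi[i]]), fmt_num(radii[i]), v$color[i],
            format(v$alpha[i]))
  }, character(1)), '</g>')

  if (isTRUE(opts$labels)) {
    lines <- c(lines, '<g id="labels" font-family="sans-serif" font-size="11">',
               vapply(seq_len(nrow(v)), function(i) {
                 sprintf('<text class="node-label" x="%s" y="%s" opacity="%s">%s</text>',
                         fmt_num(pos$px[vi[i]] + radii[i] + 3),
                         fmt_num(pos$py[vi[i]] + 4), format(v$alpha[i]),
                         xml_escape(v$regimen[i]))
               }, character(1)), '</g>')
  }

  if (isTRUE(opts$legend) && nrow(v)) {
    ord <- order(-v$value, v$regimen, method = "radix")
    y0 <- 20
    lines <- c(lines, '<g id="legend" font-family="sans-serif" font-size="10">',
               sprintf('<text x="8" y="%d" font-weight="bold">Regimens (faint = outdated)</text>', y0),
               unlist(lapply(seq_along(ord), function(k) {
                 i <- ord[k]
                 yy <- y0 + 14 * k
                 c(sprintf('<circle class="legend-node" cx="12" cy="%d" r="4" fill="%s" fill-opacity="%s"/>',
                           yy - 3, v$color[i], format(v$alpha[i])),
                   sprintf('<text class="legend-label" x="22" y="%d" opacity="%s">%s (%s)</text>',
                           yy, format(v$alpha[i]), xml_escape(v$regimen[i]),
                           v$classification[i]))
               })), '</g>')
  }

  caption <- paste(c(sprintf("Year %d", network$as_of_year), opts$caption),
                   collapse = " — ")
  lines <- c(lines,
             sprintf('<text class="caption" x="%s" y="%s" font-family="sans-serif" font-size="16" text-anchor="end">%s</text>',
                     fmt_num(opts$width - 12), fmt_num(opts$height - 12),
                     xml_escape(caption)),
             '</svg>')
  writeLines(lines, path, useBytes = TRUE)
}

hex_alpha <- function(hex, alpha) {
  m <- grDevices::col2rgb(hex)
  grDevices::rgb(m[1, ], m[2, ], m[3, ], alpha = round(255 * alpha),
                 maxColorValue = 255)
}

render_png <- function(network, layout, path, opts) {
  v <- network$vertices
  e <- network$edges
  pos <- scale_coords(layout, opts)
  vi <- match(v$regimen, pos$regimen)
  grDevices::png(path, width = opts$width, height = opts$height)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot(NA, xlim = c(0, opts$width), ylim = c(opts$height, 0),
                 axes = FALSE, xlab = "", ylab = "", asp = 1)
  if (nrow(e)) {
    offs <- edge_offsets(e)
    ia <- match(e$regimen_a, pos$regimen)
    ib <- match(e$regimen_b, pos$regimen)
    for (i in seq_len(nrow(e))) {
      x1 <- pos$px[ia[i]]; y1 <- pos$py[ia[i]]
      x2 <- pos$px[ib[i]]; y2 <- pos$py[ib[i]]
      tt <- seq(0, 1, length.out = 24)
      len <- max(sqrt((x2 - x1)^2 + (y2 - y1)^2), 1e-9)
      cx <- (x1 + x2) / 2 - offs[i] * (y2 - y1) / len
      cy <- (y1 + y2) / 2 + offs[i] * (x2 - x1) / len
      bx <- (1 - tt)^2 * x1 + 2 * (1 - tt) * tt * cx + tt^2 * x2
      by <- (1 - tt)^2 * y1 + 2 * (1 - tt) * tt * cy + tt^2 * y2
      graphics::lines(bx, by, col = hex_alpha(e$color[i], e$alpha[i]),
                      lwd = e$width[i])
    }
  }
  radii <- sqrt(v$area / pi)
  graphics::symbols(pos$px[vi], pos$py[vi], circles = radii,
                    inches = FALSE, add = TRUE,
                    bg = hex_alpha(v$color, v$alpha), fg = "#333333")
  if (isTRUE(opts$labels)) {
    graphics::text(pos$px[vi] + radii + 3, pos$py[vi], v$regimen, adj = 0,
                   cex = 0.8, col = hex_alpha("#000000", v$alpha))
  }
  graphics::text(opts$width - 12, opts$height - 12,
                 sprintf("Year %d", network$as_of_year), adj = 1)
}

#' Render one frame per year of a timeline
#'
#' Layouts are warm-started year over year from a single seed, and all
#' frames share one canvas (the union bounding box of every yearly layout),
#' so the animation is visually stable. Frame filenames
#' (`frame_<year>.<ext>`) sort chronologically; assemble a movie with any
#' external encoder.
#'
#' @param timeline An `evinet_timeline`.
#' @param dir Output directory (created if needed).
#' @param seed Layout seed.
#' @param options An [render_options()] list; `format` selects svg/png.
#' @return Tibble `year`, `file` of the written frames, invisibly.
#' @export
render_frames <- function(timeline, dir, seed = 1L,
                          options = render_options()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  yrs <- seq.int(timeline$first_year, timeline$last_year)
  layouts <- vector("list", length(yrs))
  prev <- NULL
  for (k in seq_along(yrs)) {
    prev <- layout_network(network_at(timeline, yrs[k]), seed = seed,
                           prev = prev)
    layouts[[k]] <- prev
  }
  all_x <- unlist(lapply(layouts, `[[`, "x"))
  all_y <- unlist(lapply(layouts, `[[`, "y"))
  options$bbox <- c(range(all_x), range(all_y))
  files <- purrr::map_chr(seq_along(yrs), function(k) {
    path <- file.path(dir, sprintf("frame_%d.%s", yrs[k], options$format))
    render_snapshot(network_at(timeline, yrs[k]), layouts[[k]], path, options)
    path
  })
  invisible(tibble::tibble(year = yrs, file = files))
}
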