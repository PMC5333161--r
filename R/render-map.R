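#' Render a styled pathway map as SVG and GraphML
#'
#' Nodes are drawn as filled circles at their layout coordinates and edges
#' as stroked lines; hex colours are emitted exactly as styled. When any
#' node lacks coordinates a force-directed layout is computed with the
#' given seed, so the same seed reproduces the same file byte for byte (no
#' timestamps are written). The GraphML carries the style attributes
#' (`fill`, `size`, `stroke`, `width`) for downstream graph tools.
#'
#' @param sm A `styled_map`.
#' @param out Output path prefix; writes `<out>.svg` and `<out>.graphml`.
#' @param seed Seed for the fallback layout (default 1).
#' @param formats Subset of `c("svg", "graphml")`.
#' @return Invisibly, a list of written paths.
#' @export
render_map <- function(sm, out, seed = 1L, formats = c("svg", "graphml")) {
  stopifnot(inherits(sm, "styled_map"))
  map <- sm$base
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  coords <- map_layout(map, seed)
  paths <- list()
  if ("svg" %in% formats) {
    paths$svg <- paste0(out, ".svg")
    write_map_svg(sm, coords, paths$svg)
  }
  if ("graphml" %in% formats) {
    paths$graphml <- paste0(out, ".graphml")
    write_map_graphml(sm, coords, paths$graphml)
  }
  invisible(paths)
}

map_layout <- function(map, seed) {
  x <- map$nodes$x; y <- map$nodes$y
  if (anyNA(x) || anyNA(y)) {
    g <- igraph::graph_from_data_frame(
      map$edges[, c("source", "target"), drop = FALSE], directed = FALSE,
      vertices = data.frame(name = map$nodes$id, stringsAsFactors = FALSE))
    set.seed(seed)
    lay <- igraph::layout_with_fr(g)
    # rescale into a stable drawing box
    rng <- apply(lay, 2L, function(v) diff(range(v)))
    rng[rng == 0] <- 1
    lay <- sweep(sweep(lay, 2L, apply(lay, 2L, min)), 2L, rng, "/") * 400 + 50
    x <- lay[match(map$nodes$id, igraph::V(g)$name), 1L]
    y <- lay[match(map$nodes$id, igraph::V(g)$name), 2L]
  }
  data.frame(id = map$nodes$id, x = x, y = y, stringsAsFactors = FALSE)
}

write_map_svg <- function(sm, coords, path) {
  map <- sm$base
  w <- max(coords$x) + 80
  h <- max(coords$y) + 60
  esc <- function(s) gsub("&", "&amp;", gsub("<", "&lt;", s))
  fmt <- function(v) formatC(v, format = "fg", digits = 6)
  out <- c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                          'width="%s" height="%s" viewBox="0 0 %s %s">'),
                   fmt(w), fmt(h), fmt(w), fmt(h)),
           sprintf("<!-- %s; legend: %s -->", esc(map$name), esc(sm$legend)),
           '<g font-family="sans-serif" font-size="10">')
  cx <- stats::setNames(coords$x, coords$id)
  cy <- stats::setNames(coords$y, coords$id)
  for (i in seq_len(nrow(map$edges))) {
    e <- map$edges[i, ]
    st <- sm$edge_styles[sm$edge_styles$edge_id == e$id, ]
    genes <- paste(e$genes[[1L]], collapse = ",")
    out <- c(out, sprintf(
      '<line id="%s" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
      esc(e$id), fmt(cx[[e$source]]), fmt(cy[[e$source]]),
      fmt(cx[[e$target]]), fmt(cy[[e$target]]), st$stroke, fmt(st$width)))
    if (nzchar(genes))
      out <- c(out, sprintf(
        '<text x="%s" y="%s" fill="%s" font-style="italic">%s</text>',
        fmt((cx[[e$source]] + cx[[e$target]]) / 2),
        fmt((cy[[e$source]] + cy[[e$target]]) / 2 - 4), st$stroke,
        esc(genes)))
  }
  for (i in seq_len(nrow(map$nodes))) {
    n <- map$nodes[i, ]
    st <- sm$node_styles[sm$node_styles$node_id == n$id, ]
    out <- c(out, sprintf(
      '<circle id="%s" cx="%s" cy="%s" r="%s" fill="%s" stroke="black" stroke-width="0.5"/>',
      esc(n$id), fmt(cx[[n$id]]), fmt(cy[[n$id]]), fmt(st$size), st$fill))
    out <- c(out, sprintf('<text x="%s" y="%s">%s</text>',
                          fmt(cx[[n$id]] + st$size + 2),
                          fmt(cy[[n$id]] + 3), esc(n$label)))
  }
  out <- c(out, "</g>", "</svg>")
  writeLines(out, path)
  invisible(path)
}

write_map_graphml <- function(sm, coords, path) {
  map <- sm$base
  edges <- map$edges
  vert <- data.frame(name = map$nodes$id, label = map$nodes$label,
                     fill = sm$node_styles$fill[match(map$nodes$id,
                                                      sm$node_styles$node_id)],
                     size = sm$node_styles$size[match(map$nodes$id,
                                                      sm$node_styles$node_id)],
                     x = coords$x[match(map$nodes$id, coords$id)],
                     y = coords$y[match(map$nodes$id, coords$id)],
                     stringsAsFactors = FALSE)
  edf <- data.frame(from = edges$source, to = edges$target,
                    edge_id = edges$id,
                    genes = vapply(edges$genes, paste, "", collapse = ","),
                    stroke = sm$edge_styles$stroke[match(edges$id,
                                                         sm$edge_styles$edge_id)],
                    width = sm$edge_styles$width[match(edges$id,
                                                       sm$edge_styles$edge_id)],
                    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vert)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
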