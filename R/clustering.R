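#' Correlation-profile feature vectors
#'
#' Entities are clustered not on their raw time courses but on their
#' correlation profiles: the feature vector of entity i is row i of the
#' square within-set correlation matrix (culture metrics included when
#' present), so two entities are close when they relate to everything else
#' in the same way. `NA` entries (constant profiles or short grids) are
#' imputed as 0, which is sign-neutral.
#'
#' @param cm Square `corr_matrix` with identical row and column ids.
#' @return Numeric matrix, one row per entity.
#' @export
correlation_profile_features <- function(cm) {
  if (nrow(cm) != ncol(cm) || !identical(rownames(cm), colnames(cm)))
    stop("'cm' must be a square within-set correlation matrix", call. = FALSE)
  f <- unclass(cm)
  attr(f, "condition") <- NULL
  attr(f, "n_obs") <- NULL
  if (anyNA(f)) {
    warning(sprintf("imputing %d NA correlation(s) as 0 for clustering",
                    sum(is.na(f))), call. = FALSE)
    f[is.na(f)] <- 0
  }
  f
}

#' Agglomerative clustering of feature vectors
#'
#' Average linkage (UPGMA) on Euclidean distances by default. Rows are
#' sorted lexicographically by entity id before clustering, so the merge
#' tree does not depend on input order and ties resolve reproducibly.
#'
#' @param features Numeric matrix with entity rownames (>= 2 rows).
#' @param linkage_method Agglomeration method for [stats::hclust()].
#' @param metric Distance metric for [stats::dist()].
#' @return An [stats::hclust] tree.
#' @export
hierarchical_cluster <- function(features, linkage_method = "average",
                                 metric = "euclidean") {
  features <- as.matrix(features)
  if (nrow(features) < 2L)
    stop("need at least 2 entities to cluster", call. = FALSE)
  if (is.null(rownames(features)))
    stop("'features' must have entity rownames", call. = FALSE)
  features <- features[order(rownames(features)), , drop = FALSE]
  stats::hclust(stats::dist(features, method = metric),
                method = linkage_method)
}

#' Extract the two largest flat clusters
#'
#' Cuts the tree into `k` flat clusters and keeps the two with the most
#' members as clusters A and B (the published analyses label them I/II on
#' the metabolite axis and 1/2 on the gene axis); everything else is
#' `unassigned`. Size ties are broken toward the cluster whose smallest
#' member sorts first; A is the cluster of the two that contains the
#' lexicographically smallest entity.
#'
#' @param tree An [stats::hclust] tree.
#' @param k Number of flat clusters to cut (>= 2; `k = 2` leaves nothing
#'   unassigned).
#' @param axis `"metabolite_axis"` or `"gene_axis"`.
#' @return An object of class `cluster_assignment` with fields `axis`,
#'   `labels` (named character vector over entities, values `A`, `B` or
#'   `unassigned`), `linkage` (the tree) and `order` (leaf order).
#' @export
two_largest_clusters <- function(tree, k = 2L,
                                 axis = c("metabolite_axis", "gene_axis")) {
  stopifnot(inherits(tree, "hclust"))
  axis <- match.arg(axis)
  n <- length(tree$labels)
  if (k < 2L) stop("'k' must be at least 2", call. = FALSE)
  if (k > n)
    stop(sprintf("'k' (%d) exceeds the number of leaves (%d)", k, n),
         call. = FALSE)
  cut <- stats::cutree(tree, k = k)
  sizes <- table(cut)
  smallest_member <- vapply(names(sizes), function(cl)
    min(names(cut)[cut == as.integer(cl)]), "")
  ord <- order(-as.integer(sizes), smallest_member)
  top2 <- as.integer(names(sizes))[ord[1:2]]
  # A holds the lexicographically smallest entity of the two big clusters
  first_entity <- min(names(cut)[cut %in% top2])
  a_id <- cut[[first_entity]]
  b_id <- setdiff(top2, a_id)
  labels <- rep("unassigned", n)
  names(labels) <- names(cut)
  labels[cut == a_id] <- "A"
  labels[cut == b_id] <- "B"
  structure(list(axis = axis, labels = labels, linkage = tree,
                 order = tree$labels[tree$order], k = k),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %s (k=%d): A=%d, B=%d, unassigned=%d\n",
              x$axis, x$k, sum(x$labels == "A"), sum(x$labels == "B"),
              sum(x$labels == "unassigned")))
  invisible(x)
}

#' Diverging correlation colour scale
#'
#' Linear interpolation anchored at r = -1 (blue), 0 (white) and +1 (red);
#' the mapping is odd-symmetric (the mixing weight of `color(r)` toward red
#' equals that of `color(-r)` toward blue). `NA` maps to the absent grey.
#'
#' @param r Numeric vector in `[-1, 1]` (NA allowed).
#' @return Character vector of hex colours.
#' @export
corr_color <- function(r) {
  pal <- map_palette()
  mix <- function(w, anchor) {
    a <- grDevices::col2rgb(anchor)[, 1L]
    wt <- grDevices::col2rgb(pal[["white"]])[, 1L]
    m <- round((1 - w) %o% wt + w %o% a)
    grDevices::rgb(m[, 1L], m[, 2L], m[, 3L], maxColorValue = 255)
  }
  out <- rep(pal[["grey"]], length(r))
  ok <- !is.na(r)
  if (any(ok & (r < -1 | r > 1)))
    stop("'r' must lie in [-1, 1]", call. = FALSE)
  pos <- ok & r >= 0
  neg <- ok & r < 0
  out[pos] <- mix(r[pos], pal[["red"]])
  out[neg] <- mix(-r[neg], pal[["blue"]])
  out
}

#' Render the integrated correlation heatmap
#'
#' Draws the cross-set (gene x metabolite, culture metrics appended)
#' correlation matrix with rows and columns in dendrogram leaf order, a
#' symmetric blue-white-red scale anchored at r = -1/0/+1, marginal
#' dendrograms, and underline markers on culture-metric rows/columns. The
#' ordered matrix is also written as CSV so the rendering is auditable.
#'
#' @param cross `corr_matrix` whose rows are the entities of `row_assign`
#'   and columns those of `col_assign`.
#' @param row_assign,col_assign `cluster_assignment` objects for the two
#'   axes.
#' @param out Output path prefix; writes `<out>.csv`, `<out>.svg` and
#'   (when requested) `<out>.png`.
#' @param culture_ids Entities to flag as culture metrics.
#' @param formats Subset of `c("csv", "svg", "png")`.
#' @return Invisibly, a list with the ordered matrix and written paths.
#' @export
render_heatmap <- function(cross, row_assign, col_assign, out,
                           culture_ids = character(),
                           formats = c("csv", "svg", "png")) {
  stopifnot(inherits(row_assign, "cluster_assignment"),
            inherits(col_assign, "cluster_assignment"))
  if (!setequal(rownames(cross), row_assign$order) ||
      !setequal(colnames(cross), col_assign$order))
    stop("matrix entities do not match the axis assignments", call. = FALSE)
  m <- unclass(cross)[row_assign$order, col_assign$order, drop = FALSE]
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  if ("csv" %in% formats) {
    paths$csv <- paste0(out, ".csv")
    write_correlation_matrix(m, paths$csv)
  }
  if ("svg" %in% formats) {
    paths$svg <- paste0(out, ".svg")
    write_heatmap_svg(m, row_assign, col_assign, culture_ids, paths$svg)
  }
  if ("png" %in% formats) {
    paths$png <- paste0(out, ".png")
    breaks <- seq(-1, 1, length.out = 102)
    mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
    pheatmap::pheatmap(
      m, cluster_rows = FALSE, cluster_cols = FALSE, breaks = breaks,
      color = corr_color(mids), na_col = map_palette()[["grey"]],
      filename = paths$png, silent = TRUE)
  }
  invisible(list(matrix = m, paths = paths))
}

# dendrogram segments in (leaf-position, height) coordinates
dendro_segments <- function(hc) {
  pos <- stats::setNames(match(seq_along(hc$labels), hc$order),
                         seq_along(hc$labels))
  xs <- numeric(nrow(hc$merge)); hs <- hc$height
  segs <- NULL
  node_x <- function(id) {
    if (id < 0) pos[[as.character(-id)]] else xs[id]
  }
  node_h <- function(id) if (id < 0) 0 else hs[id]
  for (i in seq_len(nrow(hc$merge))) {
    l <- hc$merge[i, 1L]; r <- hc$merge[i, 2L]
    xl <- node_x(l); xr <- node_x(r)
    xs[i] <- (xl + xr) / 2
    segs <- rbind(segs,
                  c(xl, node_h(l), xl, hs[i]),
                  c(xr, node_h(r), xr, hs[i]),
                  c(xl, hs[i], xr, hs[i]))
  }
  segs
}

write_heatmap_svg <- function(m, row_assign, col_assign, culture_ids, path) {
  cell <- 14; margin <- 70; dsize <- 60
  nr <- nrow(m); nc <- ncol(m)
  w <- margin + dsize + nc * cell + 10
  h <- margin + dsize + nr * cell + 10
  x0 <- dsize + 5; y0 <- dsize + 5
  esc <- function(s) gsub("&", "&amp;", gsub("<", "&lt;", s))
  out <- c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                          'width="%d" height="%d" viewBox="0 0 %d %d">'),
                   w + margin, h, w + margin, h),
           '<g font-family="sans-serif" font-size="9">')
  cols <- matrix(corr_color(as.vector(m)), nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    out <- c(out, sprintf(
      '<rect x="%g" y="%g" width="%d" height="%d" fill="%s"/>',
      x0 + (j - 1) * cell, y0 + (i - 1) * cell, cell, cell, cols[i, j]))
  # labels; culture metrics get an underline marker
  for (i in seq_len(nr)) {
    lab <- rownames(m)[i]
    y <- y0 + (i - 0.3) * cell
    out <- c(out, sprintf('<text x="%g" y="%g">%s</text>',
                          x0 + nc * cell + 4, y, esc(lab)))
    if (lab %in% culture_ids)
      out <- c(out, sprintf(
        '<line x1="%g" y1="%g" x2="%g" y2="%g" stroke="black" class="culture-underline"/>',
        x0 + nc * cell + 4, y + 2, x0 + nc * cell + 4 + 7 * nchar(lab), y + 2))
  }
  for (j in seq_len(nc)) {
    lab <- colnames(m)[j]
    x <- x0 + (j - 0.3) * cell
    out <- c(out, sprintf(
      '<text x="%g" y="%g" transform="rotate(90 %g %g)">%s</text>',
      x, y0 + nr * cell + 4, x, y0 + nr * cell + 4, esc(lab)))
    if (lab %in% culture_ids)
      out <- c(out, sprintf(
        '<line x1="%g" y1="%g" x2="%g" y2="%g" stroke="black" class="culture-underline"/>',
        x - 2, y0 + nr * cell + 4, x - 2,
        y0 + nr * cell + 4 + 7 * nchar(lab)))
  }
  scale_segs <- function(segs, extent, size) {
    segs[, c(2, 4)] <- size * (1 - segs[, c(2, 4)] /
                                 max(segs[, c(2, 4)], 1e-12))
    segs
  }
  # column dendrogram on top, row dendrogram on the left
  cs <- scale_segs(dendro_segments(col_assign$linkage), nc, dsize)
  for (i in seq_len(nrow(cs)))
    out <- c(out, sprintf(
      '<line x1="%g" y1="%g" x2="%g" y2="%g" stroke="black" stroke-width="0.7"/>',
      x0 + (cs[i, 1] - 0.5) * cell, cs[i, 2],
      x0 + (cs[i, 3] - 0.5) * cell, cs[i, 4]))
  rs <- scale_segs(dendro_segments(row_assign$linkage), nr, dsize)
  for (i in seq_len(nrow(rs)))
    out <- c(out, sprintf(
      '<line x1="%g" y1="%g" x2="%g" y2="%g" stroke="black" stroke-width="0.7"/>',
      rs[i, 2], y0 + (rs[i, 1] - 0.5) * cell,
      rs[i, 4], y0 + (rs[i, 3] - 0.5) * cell))
  out <- c(out, "</g>", "</svg>")
  writeLines(out, path)
  invisible(path)
}

#' Write a linkage tree as JSON
#'
#' Serialises an [stats::hclust] tree as merge pairs (negative = leaf
#' index), merge heights, labels and leaf order.
#'
#' @param tree An [stats::hclust] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_linkage_json <- function(tree, path) {
  stopifnot(inherits(tree, "hclust"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(labels = tree$labels,
         merge = apply(tree$merge, 1L, as.list),
         height = tree$height, order = tree$order),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
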