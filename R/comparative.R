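#' Fixed display palette
#'
#' Hex colours used by all map and heatmap renderers: orange / light blue
#' for the two large clusters, red / green / blue for the comparative
#' correlation bins, white for metabolites and grey for genes absent from
#' an analysis.
#'
#' @return Named character vector of hex colours.
#' @export
map_palette <- function() {
  c(orange = "#F5A623", lightblue = "#9BD7E5", red = "#D0021B",
    green = "#2E9E3F", blue = "#2257C4", white = "#FFFFFF",
    grey = "#BDBDBD")
}

BIN_LEVELS <- c("strong_neg", "neg", "weak_pos", "pos", "strong_pos", "na")

# display colour word per bin, as used in the variation report
bin_color_word <- function(bin) {
  c(strong_pos = "bold_red", pos = "red", weak_pos = "green", neg = "blue",
    strong_neg = "bold_blue", na = "na")[as.character(bin)]
}

#' Assign a between-condition correlation to its display bin
#'
#' The five comparative display bins: bold/big red for `r > 0.9`, red for
#' `0.5 < r <= 0.9`, green (uncorrelated) for `0 <= r <= 0.5`, blue for
#' `-0.5 <= r < 0`, bold/big blue for `r < -0.5`; `NA` maps to `na`. Note
#' the deliberate asymmetry: the positive side splits at 0.9 and 0.5, the
#' negative side only at -0.5. Boundary values attach to the inner (weaker)
#' bin and 0 joins `weak_pos`.
#'
#' @param r Numeric vector in `[-1, 1]`, NA allowed.
#' @return Factor with levels
#'   `strong_neg, neg, weak_pos, pos, strong_pos, na`.
#' @export
assign_bin <- function(r) {
  r <- as.numeric(r)
  if (any(!is.na(r) & (r < -1 | r > 1)))
    stop("'r' must lie in [-1, 1]", call. = FALSE)
  out <- ifelse(is.na(r), "na",
         ifelse(r > 0.9, "strong_pos",
         ifelse(r > 0.5, "pos",
         ifelse(r >= 0, "weak_pos",
         ifelse(r >= -0.5, "neg", "strong_neg")))))
  factor(out, levels = BIN_LEVELS)
}

#' Correlation of one entity's profile between two conditions
#'
#' Pearson r of the entity's replicate-mean time course under `cond_a`
#' against the same entity under `cond_b`, on the shared time grid. An r
#' near 1 means the perturbation left the temporal profile unchanged.
#'
#' @param d An `omics_dataset`.
#' @param entity_id Entity present under both conditions.
#' @param cond_a,cond_b Condition labels.
#' @param min_n Minimum shared-grid length (default 3).
#' @return r in `[-1, 1]`, or `NA` (constant profile or short grid).
#' @export
between_condition_r <- function(d, entity_id, cond_a, cond_b, min_n = 3L) {
  a <- get_profile(d, entity_id, cond_a)
  b <- get_profile(d, entity_id, cond_b)
  grid <- common_grid(a, b)
  if (length(grid) < min_n) return(NA_real_)
  ma <- mean_profile(a); mb <- mean_profile(b)
  pearson_r(ma$mean[match(grid, ma$time)], mb$mean[match(grid, mb$time)],
            min_n = min_n)
}

new_styled_map <- function(base, node_styles, edge_styles, legend) {
  structure(list(base = base, node_styles = node_styles,
                 edge_styles = edge_styles, legend = legend),
            class = "styled_map")
}

#' @export
print.styled_map <- function(x, ...) {
  cat(sprintf("<styled_map> '%s' (%s): %d nodes, %d edges\n", x$base$name,
              x$legend, nrow(x$node_styles), nrow(x$edge_styles)))
  invisible(x)
}

NODE_RADIUS <- 10
EDGE_WIDTH <- 2
STRONG_NODE_SCALE <- 1.6
STRONG_EDGE_SCALE <- 2.5

#' Project cluster labels onto a pathway map
#'
#' Colours metabolite nodes by their metabolite-axis cluster (A -> orange,
#' B -> light blue) and reaction edges by the cluster of their gene labels.
#' Metabolites absent from the analysis stay white and genes grey. An edge
#' whose genes fall in conflicting clusters is drawn grey and the conflict
#' is reported via a warning.
#'
#' @param map A [pathway_map]; node ids are matched against metabolite
#'   entity ids and edge gene labels against gene entity ids.
#' @param met_assign `cluster_assignment` for the metabolite axis.
#' @param gene_assign `cluster_assignment` for the gene axis.
#' @return A `styled_map`.
#' @export
style_by_cluster <- function(map, met_assign, gene_assign) {
  stopifnot(inherits(map, "pathway_map"),
            inherits(met_assign, "cluster_assignment"),
            inherits(gene_assign, "cluster_assignment"))
  pal <- map_palette()
  cluster_fill <- c(A = pal[["orange"]], B = pal[["lightblue"]])
  node_fill <- vapply(map$nodes$id, function(id) {
    cl <- met_assign$labels[id]
    if (!is.na(cl) && cl %in% c("A", "B")) cluster_fill[[cl]] else
      pal[["white"]]
  }, "")
  node_styles <- data.frame(node_id = map$nodes$id, fill = unname(node_fill),
                            size = NODE_RADIUS, stringsAsFactors = FALSE)
  conflicts <- character()
  edge_stroke <- character(nrow(map$edges))
  for (i in seq_len(nrow(map$edges))) {
    genes <- map$edges$genes[[i]]
    cls <- unique(gene_assign$labels[intersect(genes,
                                               names(gene_assign$labels))])
    cls <- cls[cls %in% c("A", "B")]
    if (length(cls) == 1L) {
      edge_stroke[i] <- cluster_fill[[cls]]
    } else {
      if (length(cls) > 1L) conflicts <- c(conflicts, map$edges$id[i])
      edge_stroke[i] <- pal[["grey"]]
    }
  }
  if (length(conflicts))
    warning(sprintf("edge(s) with genes in conflicting clusters drawn grey: %s",
                    paste(conflicts, collapse = ", ")), call. = FALSE)
  edge_styles <- data.frame(edge_id = map$edges$id, stroke = edge_stroke,
                            width = EDGE_WIDTH, stringsAsFactors = FALSE)
  new_styled_map(map, node_styles, edge_styles, "cluster membership")
}

bin_node_style <- function(bin) {
  pal <- map_palette()
  fill <- c(strong_pos = pal[["red"]], pos = pal[["red"]],
            weak_pos = pal[["green"]], neg = pal[["blue"]],
            strong_neg = pal[["blue"]], na = pal[["white"]])
  size <- ifelse(bin %in% c("strong_pos", "strong_neg"),
                 NODE_RADIUS * STRONG_NODE_SCALE, NODE_RADIUS)
  list(fill = unname(fill[as.character(bin)]), size = size)
}

bin_edge_style <- function(bin) {
  pal <- map_palette()
  stroke <- c(strong_pos = pal[["red"]], pos = pal[["red"]],
              weak_pos = pal[["green"]], neg = pal[["blue"]],
              strong_neg = pal[["blue"]], na = pal[["grey"]])
  width <- ifelse(bin %in% c("strong_pos", "strong_neg"),
                  EDGE_WIDTH * STRONG_EDGE_SCALE, EDGE_WIDTH)
  list(stroke = unname(stroke[as.character(bin)]), width = width)
}

#' Comparative between-condition map
#'
#' For every mapped metabolite and gene, correlates its time course under
#' `cond_a` with that under `cond_b` and styles the map by the resulting
#' display bin: red shades for conserved profiles, green for uncorrelated,
#' blue for inverted; strong bins (|r| past the outer thresholds) are drawn
#' as enlarged nodes / bold edges. Entities absent from the dataset render
#' white (metabolites) or grey (genes). Edges aggregating several genes
#' (isozymes) take the bin of the gene with the most extreme |r|.
#'
#' @param map A [pathway_map].
#' @param d An `omics_dataset` containing both conditions.
#' @param cond_a,cond_b Condition labels.
#' @param min_n Minimum shared-grid length.
#' @return List with `styled` (a `styled_map`), `bins` (data.frame
#'   `entity_id, kind, r, bin` for every mapped entity) and `unmapped`
#'   (dataset entities not on the map).
#' @export
comparative_map <- function(map, d, cond_a, cond_b, min_n = 3L) {
  stopifnot(inherits(map, "pathway_map"), inherits(d, "omics_dataset"))
  for (cc in c(cond_a, cond_b))
    if (!cc %in% dataset_conditions(d))
      stop(sprintf("unknown condition '%s'", cc), call. = FALSE)
  have <- function(id) {
    !is.null(d$profiles[[profile_key(id, cond_a)]]) &&
      !is.null(d$profiles[[profile_key(id, cond_b)]])
  }
  ent_r <- function(id) {
    if (!have(id)) return(NA_real_)
    between_condition_r(d, id, cond_a, cond_b, min_n = min_n)
  }
  node_r <- vapply(map$nodes$id, ent_r, 0)
  node_bin <- assign_bin(node_r)
  ns <- bin_node_style(node_bin)
  # a node never seen in the dataset is absent (white), not weak/na-binned
  node_styles <- data.frame(node_id = map$nodes$id, fill = ns$fill,
                            size = ns$size, stringsAsFactors = FALSE)
  all_genes <- sort(unique(unlist(map$edges$genes)))
  gene_r <- vapply(all_genes, ent_r, 0)
  gene_bin <- assign_bin(gene_r)
  edge_bin <- factor(rep("na", nrow(map$edges)), levels = BIN_LEVELS)
  edge_r <- rep(NA_real_, nrow(map$edges))
  for (i in seq_len(nrow(map$edges))) {
    rs <- gene_r[match(map$edges$genes[[i]], all_genes)]
    rs <- rs[!is.na(rs)]
    if (length(rs)) {
      edge_r[i] <- rs[which.max(abs(rs))]
      edge_bin[i] <- assign_bin(edge_r[i])
    }
  }
  es <- bin_edge_style(edge_bin)
  edge_styles <- data.frame(edge_id = map$edges$id, stroke = es$stroke,
                            width = es$width, stringsAsFactors = FALSE)
  bins <- rbind(
    data.frame(entity_id = map$nodes$id, kind = "metabolite",
               r = unname(node_r), bin = as.character(node_bin),
               stringsAsFactors = FALSE),
    data.frame(entity_id = all_genes, kind = "gene", r = unname(gene_r),
               bin = as.character(gene_bin), stringsAsFactors = FALSE))
  bins <- bins[order(bins$kind, bins$entity_id), , drop = FALSE]
  rownames(bins) <- NULL
  measured <- dataset_entities(d, kind = c("metabolite", "gene"))
  unmapped <- sort(setdiff(measured, c(map$nodes$id, all_genes)))
  styled <- new_styled_map(map, node_styles, edge_styles,
                           sprintf("correlation %s vs %s", cond_a, cond_b))
  list(styled = styled, bins = bins, unmapped = unmapped)
}

#' Colour-variation summary between two comparative maps
#'
#' Summarises how each entity's display bin changes between two comparative
#' analyses sharing the same reference condition (e.g. control/5mM vs
#' control/10mM): each entity is labeled `colourA/colourB` and entities are
#' grouped by that variation pattern, metabolites and genes separately.
#'
#' @param bins_ab,bins_ac Bin tables from [comparative_map()] over the same
#'   entity set.
#' @return data.frame with columns `pattern` (e.g. `"red/green"`), `kind`,
#'   `n` and `entities` (comma-joined ids), sorted by kind then pattern.
#' @export
variation_table <- function(bins_ab, bins_ac) {
  if (!setequal(paste(bins_ab$entity_id, bins_ab$kind),
                paste(bins_ac$entity_id, bins_ac$kind)))
    stop("the two bin tables must cover the same entities", call. = FALSE)
  key <- paste(bins_ac$entity_id, bins_ac$kind)
  m <- match(paste(bins_ab$entity_id, bins_ab$kind), key)
  pattern <- paste(bin_color_word(bins_ab$bin),
                   bin_color_word(bins_ac$bin[m]), sep = "/")
  agg <- stats::aggregate(bins_ab$entity_id,
                          by = list(pattern = pattern, kind = bins_ab$kind),
                          FUN = function(v) paste(sort(v), collapse = ","))
  names(agg)[3L] <- "entities"
  agg$n <- vapply(strsplit(agg$entities, ","), length, 1L)
  agg <- agg[order(agg$kind, agg$pattern), c("pattern", "kind", "n",
                                             "entities")]
  rownames(agg) <- NULL
  agg
}

#' Export a cluster's gene list for external enrichment analysis
#'
#' Writes one gene symbol per line, sorted, ready for submission to GO /
#' PANTHER enrichment services (the enrichment itself is out of scope).
#'
#' @param assign A gene-axis `cluster_assignment`.
#' @param cluster `"A"` or `"B"`.
#' @param path Output path.
#' @param exclude Entity ids to drop (e.g. culture metrics inserted on the
#'   gene axis).
#' @return `path`, invisibly.
#' @export
export_cluster_gene_list <- function(assign, cluster, path,
                                     exclude = character()) {
  stopifnot(inherits(assign, "cluster_assignment"))
  if (assign$axis != "gene_axis")
    stop("gene list export requires a gene-axis assignment", call. = FALSE)
  if (!cluster %in% c("A", "B"))
    stop(sprintf("unknown cluster label '%s'", cluster), call. = FALSE)
  genes <- sort(setdiff(names(assign$labels)[assign$labels == cluster],
                        exclude))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(genes, path)
  invisible(path)
}
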