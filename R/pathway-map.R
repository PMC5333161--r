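#' Construct a metabolic pathway map
#'
#' Maps follow the node/edge semantics of metabolic pathway mapping systems
#' in which metabolites are drawn as nodes and the genes encoding the
#' enzymes of a reaction label the edge connecting its substrate and
#' product.
#'
#' @param nodes data.frame with columns `id` (unique), `compound_ids`
#'   (list-column of external identifiers, e.g. KEGG C-numbers; may be
#'   empty), `label`, and optional numeric `x`, `y` layout coordinates.
#' @param edges data.frame with columns `id`, `source`, `target` (node ids),
#'   `genes` (list-column of gene symbols, may be empty) and logical
#'   `reversible`.
#' @param name Map name.
#' @return An object of class `pathway_map`.
#' @export
pathway_map <- function(nodes, edges, name = "pathway") {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(nodes)))
    stop("nodes need 'id' and 'label' columns", call. = FALSE)
  if (is.null(nodes$compound_ids)) nodes$compound_ids <- I(rep(list(character()),
                                                               nrow(nodes)))
  if (is.null(nodes$x)) nodes$x <- NA_real_
  if (is.null(nodes$y)) nodes$y <- NA_real_
  if (anyDuplicated(nodes$id))
    stop("node ids must be unique", call. = FALSE)
  if (nrow(edges)) {
    if (!all(c("id", "source", "target") %in% names(edges)))
      stop("edges need 'id', 'source' and 'target' columns", call. = FALSE)
    if (is.null(edges$genes)) edges$genes <- I(rep(list(character()),
                                                   nrow(edges)))
    if (is.null(edges$reversible)) edges$reversible <- FALSE
    dangling <- !(edges$source %in% nodes$id) | !(edges$target %in% nodes$id)
    if (any(dangling))
      stop(sprintf("validation error: edge(s) with unknown endpoint: %s",
                   paste(edges$id[dangling], collapse = ", ")), call. = FALSE)
    if (anyDuplicated(edges$id))
      stop("edge ids must be unique", call. = FALSE)
  } else {
    edges <- data.frame(id = character(), source = character(),
                        target = character(), stringsAsFactors = FALSE)
    edges$genes <- I(list())
    edges$reversible <- logical()
  }
  structure(list(nodes = nodes, edges = edges, name = name),
            class = "pathway_map")
}

#' @export
print.pathway_map <- function(x, ...) {
  cat(sprintf("<pathway_map> '%s': %d metabolite nodes, %d reaction edges\n",
              x$name, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Load a pathway map from JSON or KGML
#'
#' The native format is JSON:
#' `{"name", "nodes":[{"id","compound_ids","label","x","y"}],`
#' `"edges":[{"id","source","target","genes","reversible"}]}`.
#' KGML (KEGG XML) import is best-effort: compound entries become nodes;
#' each reaction contributes one edge per substrate/product pair, labeled
#' with the graphics names of the gene entries attached to that reaction.
#'
#' @param path File path.
#' @param format `"json"` or `"kgml"`.
#' @return A [pathway_map].
#' @export
load_pathway_map <- function(path, format = c("json", "kgml")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "json") read_map_json(path) else read_map_kgml(path)
}

read_map_json <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop(sprintf("parse error in %s: %s",
                                                   path, conditionMessage(e)),
                                           call. = FALSE))
  chr1 <- function(x, default = NA_character_)
    if (is.null(x)) default else as.character(x)
  num1 <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  nodes <- do.call(rbind, lapply(obj$nodes, function(n) {
    data.frame(id = chr1(n$id), label = chr1(n$label, chr1(n$id)),
               x = num1(n$x), y = num1(n$y), stringsAsFactors = FALSE)
  }))
  nodes$compound_ids <- I(lapply(obj$nodes, function(n)
    as.character(unlist(n$compound_ids))))
  edges <- if (length(obj$edges)) {
    e <- do.call(rbind, lapply(obj$edges, function(ed) {
      data.frame(id = chr1(ed$id), source = chr1(ed$source),
                 target = chr1(ed$target),
                 reversible = isTRUE(ed$reversible), stringsAsFactors = FALSE)
    }))
    e$genes <- I(lapply(obj$edges, function(ed)
      as.character(unlist(ed$genes))))
    e
  } else NULL
  pathway_map(nodes, edges, name = chr1(obj$name, "pathway"))
}

read_map_kgml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop(sprintf("parse error in %s: %s",
                                                   path, conditionMessage(e)),
                                           call. = FALSE))
  entries <- xml2::xml_find_all(doc, ".//entry")
  etype <- xml2::xml_attr(entries, "type")
  gfx_name <- vapply(entries, function(e) {
    g <- xml2::xml_find_first(e, "./graphics")
    if (inherits(g, "xml_missing")) NA_character_ else xml2::xml_attr(g, "name")
  }, "")
  gfx_xy <- t(vapply(entries, function(e) {
    g <- xml2::xml_find_first(e, "./graphics")
    if (inherits(g, "xml_missing")) c(NA_real_, NA_real_) else
      as.numeric(c(xml2::xml_attr(g, "x"), xml2::xml_attr(g, "y")))
  }, c(0, 0)))
  comp <- which(etype == "compound")
  nodes <- data.frame(
    id = xml2::xml_attr(entries[comp], "id"),
    label = sub(",.*$", "", ifelse(is.na(gfx_name[comp]), "", gfx_name[comp])),
    x = gfx_xy[comp, 1L], y = gfx_xy[comp, 2L], stringsAsFactors = FALSE)
  nodes$compound_ids <- I(lapply(strsplit(
    xml2::xml_attr(entries[comp], "name"), " "), function(v)
      sub("^cpd:", "", v)))
  # gene entries carry a 'reaction' attribute tying enzymes to reactions
  gene_idx <- which(etype == "gene")
  gene_rxn <- xml2::xml_attr(entries[gene_idx], "reaction")
  gene_lab <- sub(",.*$", "", ifelse(is.na(gfx_name[gene_idx]), "",
                                     gfx_name[gene_idx]))
  reactions <- xml2::xml_find_all(doc, ".//reaction")
  edges <- NULL
  glist <- list()
  for (r in reactions) {
    rname <- xml2::xml_attr(r, "name")
    rev <- identical(xml2::xml_attr(r, "type"), "reversible")
    genes <- character()
    if (length(gene_idx)) {
      hit <- vapply(gene_rxn, function(rr)
        !is.na(rr) && rname %in% strsplit(rr, " ")[[1L]], TRUE)
      genes <- gene_lab[hit]
    }
    subs <- xml2::xml_attr(xml2::xml_find_all(r, "./substrate"), "id")
    prods <- xml2::xml_attr(xml2::xml_find_all(r, "./product"), "id")
    for (s in subs) for (p in prods) {
      edges <- rbind(edges, data.frame(
        id = sprintf("%s_%s_%s", rname, s, p), source = s, target = p,
        reversible = rev, stringsAsFactors = FALSE))
      glist[[length(glist) + 1L]] <- genes
    }
  }
  if (!is.null(edges)) edges$genes <- I(glist)
  pname <- xml2::xml_attr(xml2::xml_find_first(doc, "/pathway"), "title")
  pathway_map(nodes, edges,
              name = if (is.na(pname)) "kgml pathway" else pname)
}

#' Write a pathway map to its native JSON format
#' @param map A [pathway_map].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pathway_map <- function(map, path) {
  stopifnot(inherits(map, "pathway_map"))
  nodes <- lapply(seq_len(nrow(map$nodes)), function(i) {
    n <- map$nodes[i, ]
    out <- list(id = n$id, compound_ids = as.list(n$compound_ids[[1L]]),
                label = n$label)
    if (!is.na(n$x)) out$x <- n$x
    if (!is.na(n$y)) out$y <- n$y
    out
  })
  edges <- lapply(seq_len(nrow(map$edges)), function(i) {
    e <- map$edges[i, ]
    list(id = e$id, source = e$source, target = e$target,
         genes = as.list(e$genes[[1L]]), reversible = e$reversible)
  })
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(name = map$name, nodes = nodes, edges = edges),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
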