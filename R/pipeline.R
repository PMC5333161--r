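#' Build a run configuration
#'
#' Collects every tunable of the pipeline in one auditable place:
#' classifier thresholds, clustering choices, the minimum shared time grid,
#' and the seed used for every stochastic step. Values can also be loaded
#' from a YAML file with [read_run_config()].
#'
#' @param out_dir Output directory for all stage products.
#' @param seed Integer seed (mandatory; drives simulation and layouts).
#' @param profiles_csv Path to the tidy profiles CSV (written by
#'   [run_simulate()] or supplied by the user).
#' @param map_json Path to the pathway map JSON (optional; map stages
#'   require it).
#' @param conditions Condition labels, first label = control.
#' @param const_cv,net_change,step_tol Pattern classifier thresholds.
#' @param linkage,metric Clustering linkage method and distance metric.
#' @param k Number of flat clusters to cut per axis; the two largest become
#'   clusters A and B. The default 3 accommodates the third correlation
#'   orientation that the inserted culture metrics introduce (extracellular
#'   glucose anti-correlates with both omics blocks), so an outlying
#'   culture metric lands in the unassigned remainder instead of capturing
#'   one of the two clusters.
#' @param min_grid Minimum shared-grid length for any correlation.
#' @param n_metabolites,n_genes,n_replicates,noise_cv Synthetic generator
#'   settings used by [run_simulate()].
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed, profiles_csv = NULL, map_json = NULL,
                       conditions = c("0mM", "5mM", "10mM"),
                       const_cv = 0.10, net_change = 0.20, step_tol = 0.05,
                       linkage = "average", metric = "euclidean", k = 3L,
                       min_grid = 3L, n_metabolites = 34L, n_genes = 40L,
                       n_replicates = 3L, noise_cv = 0.05) {
  if (missing(seed) || !is.finite(seed))
    stop("'seed' is mandatory", call. = FALSE)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 profiles_csv = profiles_csv, map_json = map_json,
                 conditions = conditions, const_cv = const_cv,
                 net_change = net_change, step_tol = step_tol,
                 linkage = linkage, metric = metric, k = as.integer(k),
                 min_grid = as.integer(min_grid),
                 n_metabolites = as.integer(n_metabolites),
                 n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates),
                 noise_cv = noise_cv),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file; keys as in [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

# default dose ladder: control, mild and strong perturbation (0/5/10 mM-like)
dose_strengths <- function(n) {
  base <- c(0, 0.3, 0.7)
  if (n <= 3L) base[seq_len(n)] else c(base, seq(0.8, 1, length.out = n - 3L))
}

# every stage writes a manifest: inputs, parameters, seed, output hashes
write_manifest <- function(cfg, stage, inputs, outputs, dir) {
  outputs <- unlist(outputs, use.names = FALSE)
  hashes <- as.list(tools::md5sum(outputs))
  names(hashes) <- basename(names(hashes))
  params <- cfg[setdiff(names(cfg), c("out_dir", "profiles_csv",
                                      "map_json"))]
  path <- file.path(dir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(list(stage = stage, inputs = inputs, params = params,
                            seed = cfg$seed, outputs = hashes),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

stage_dir <- function(cfg, stage) {
  d <- file.path(cfg$out_dir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

require_file <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    stop(sprintf("%s not found: %s", what,
                 if (is.null(path)) "<unset>" else path), call. = FALSE)
  path
}

#' Stage: simulate a synthetic dataset
#'
#' Writes `profiles.csv`, `truth.json` and a manifest under
#' `<out_dir>/simulate/`, and points `profiles_csv` in the returned config
#' at the simulated file.
#'
#' @param cfg A `run_config`.
#' @return List with `config` (updated), `dataset`, `truth`, `paths`.
#' @export
run_simulate <- function(cfg) {
  d <- stage_dir(cfg, "simulate")
  scfg <- synthetic_config(
    n_metabolites = cfg$n_metabolites, n_genes = cfg$n_genes,
    n_replicates = cfg$n_replicates, noise_cv = cfg$noise_cv,
    conditions = data.frame(
      label = cfg$conditions,
      perturbation_strength = dose_strengths(length(cfg$conditions))),
    seed = cfg$seed)
  sim <- generate_synthetic(scfg)
  paths <- list(profiles = file.path(d, "profiles.csv"),
                truth = file.path(d, "truth.json"))
  write_dataset(sim$dataset, paths$profiles)
  jsonlite::write_json(sim$truth, paths$truth, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths$manifest <- write_manifest(cfg, "simulate", list(), paths[1:2], d)
  cfg$profiles_csv <- paths$profiles
  list(config = cfg, dataset = sim$dataset, truth = sim$truth, paths = paths)
}

#' Stage: classify temporal patterns
#'
#' Reads the profiles CSV and writes `patterns.csv`
#' (entity_id, entity_kind, condition, pattern, net_change_value, cv_value)
#' plus a manifest under `<out_dir>/classify/`.
#'
#' @param cfg A `run_config` with `profiles_csv` set.
#' @return List with `patterns` and `paths`.
#' @export
run_classify <- function(cfg) {
  d <- stage_dir(cfg, "classify")
  ds <- read_profiles(require_file(cfg$profiles_csv, "profiles CSV"))
  pat <- classify_dataset(ds, const_cv = cfg$const_cv,
                          net_change = cfg$net_change,
                          step_tol = cfg$step_tol)
  paths <- list(patterns = file.path(d, "patterns.csv"))
  utils::write.csv(pat, paths$patterns, row.names = FALSE, quote = FALSE)
  paths$manifest <- write_manifest(cfg, "classify",
                                   list(profiles = cfg$profiles_csv),
                                   paths["patterns"], d)
  list(patterns = pat, paths = paths)
}

#' Stage: correlation matrices, clustering and heatmap
#'
#' For one condition (default: the control), computes the within-set
#' metabolite and gene correlation matrices with culture metrics inserted
#' on both axes, clusters each axis by its correlation profiles, extracts
#' the two largest clusters, and renders the integrated gene x metabolite
#' heatmap. Writes matrices, cluster assignments, linkage trees, the
#' ordered heatmap CSV/SVG/PNG and a manifest under
#' `<out_dir>/correlate/<condition>/`.
#'
#' @param cfg A `run_config` with `profiles_csv` set.
#' @param condition Condition label (default: first configured).
#' @return List with the matrices, assignments and `paths`.
#' @export
run_correlate <- function(cfg, condition = cfg$conditions[1L]) {
  d <- stage_dir(cfg, file.path("correlate", condition))
  ds <- read_profiles(require_file(cfg$profiles_csv, "profiles CSV"))
  culture <- dataset_entities(ds, kind = "culture_metric",
                              condition = condition)
  cm_met <- correlation_matrix(ds, condition, rows = "metabolite",
                               include_culture = TRUE, min_n = cfg$min_grid)
  cm_gene <- correlation_matrix(ds, condition, rows = "gene",
                                include_culture = TRUE, min_n = cfg$min_grid)
  cross <- correlation_matrix(ds, condition, rows = "gene",
                              cols = "metabolite", include_culture = TRUE,
                              min_n = cfg$min_grid)
  met_assign <- two_largest_clusters(
    hierarchical_cluster(correlation_profile_features(cm_met),
                         cfg$linkage, cfg$metric),
    k = cfg$k, axis = "metabolite_axis")
  gene_assign <- two_largest_clusters(
    hierarchical_cluster(correlation_profile_features(cm_gene),
                         cfg$linkage, cfg$metric),
    k = cfg$k, axis = "gene_axis")
  paths <- list(met_matrix = file.path(d, "metabolite_matrix.csv"),
                gene_matrix = file.path(d, "gene_matrix.csv"),
                cross_matrix = file.path(d, "cross_matrix.csv"),
                assignments = file.path(d, "cluster_assignments.csv"),
                met_linkage = file.path(d, "metabolite_linkage.json"),
                gene_linkage = file.path(d, "gene_linkage.json"))
  write_correlation_matrix(cm_met, paths$met_matrix)
  write_correlation_matrix(cm_gene, paths$gene_matrix)
  write_correlation_matrix(cross, paths$cross_matrix)
  assign_df <- rbind(
    data.frame(entity_id = names(met_assign$labels), axis = "metabolite_axis",
               cluster = unname(met_assign$labels),
               stringsAsFactors = FALSE),
    data.frame(entity_id = names(gene_assign$labels), axis = "gene_axis",
               cluster = unname(gene_assign$labels),
               stringsAsFactors = FALSE))
  assign_df <- assign_df[order(assign_df$axis, assign_df$entity_id), ]
  utils::write.csv(assign_df, paths$assignments, row.names = FALSE,
                   quote = FALSE)
  write_linkage_json(met_assign$linkage, paths$met_linkage)
  write_linkage_json(gene_assign$linkage, paths$gene_linkage)
  hm <- render_heatmap(cross, gene_assign, met_assign,
                       out = file.path(d, "heatmap"),
                       culture_ids = culture)
  paths <- c(paths, hm$paths["csv"], heatmap_svg = hm$paths$svg)
  text_paths <- paths
  if (!is.null(hm$paths$png)) paths$heatmap_png <- hm$paths$png
  paths$manifest <- write_manifest(cfg, paste0("correlate_", condition),
                                   list(profiles = cfg$profiles_csv),
                                   text_paths, d)
  list(met_matrix = cm_met, gene_matrix = cm_gene, cross_matrix = cross,
       met_assign = met_assign, gene_assign = gene_assign, paths = paths)
}

#' Stage: cluster-styled pathway map
#'
#' Styles the pathway map by the cluster assignments (orange / light blue /
#' absent) and renders it to SVG and GraphML, plus gene lists of both
#' clusters for external enrichment submission, under `<out_dir>/map/`.
#'
#' @param cfg A `run_config` with `map_json` set.
#' @param met_assign,gene_assign `cluster_assignment`s (e.g. from
#'   [run_correlate()]).
#' @return List with `styled` and `paths`.
#' @export
run_map <- function(cfg, met_assign, gene_assign) {
  d <- stage_dir(cfg, "map")
  map <- load_pathway_map(require_file(cfg$map_json, "pathway map JSON"))
  styled <- style_by_cluster(map, met_assign, gene_assign)
  rendered <- render_map(styled, file.path(d, "cluster_map"),
                         seed = cfg$seed)
  paths <- list(svg = rendered$svg, graphml = rendered$graphml,
                genes_A = file.path(d, "cluster_A_genes.txt"),
                genes_B = file.path(d, "cluster_B_genes.txt"))
  culture <- if (!is.null(cfg$profiles_csv) && file.exists(cfg$profiles_csv))
    dataset_entities(read_profiles(cfg$profiles_csv),
                     kind = "culture_metric") else character()
  export_cluster_gene_list(gene_assign, "A", paths$genes_A,
                           exclude = culture)
  export_cluster_gene_list(gene_assign, "B", paths$genes_B,
                           exclude = culture)
  paths$manifest <- write_manifest(cfg, "map", list(map = cfg$map_json),
                                   paths[1:4], d)
  list(styled = styled, paths = paths)
}

#' Stage: comparative maps and variation report
#'
#' Builds the comparative map of `cond_a` vs `cond_b` (and, when `cond_c`
#' is given, of `cond_a` vs `cond_c` plus the colour-variation summary
#' between the two comparisons), under `<out_dir>/compare/`.
#'
#' @param cfg A `run_config` with `profiles_csv` and `map_json` set.
#' @param cond_a Reference condition (e.g. control).
#' @param cond_b,cond_c Comparison conditions.
#' @return List with `bins_ab`, optionally `bins_ac` and `variation`, and
#'   `paths`.
#' @export
run_compare <- function(cfg, cond_a, cond_b, cond_c = NULL) {
  d <- stage_dir(cfg, "compare")
  ds <- read_profiles(require_file(cfg$profiles_csv, "profiles CSV"))
  map <- load_pathway_map(require_file(cfg$map_json, "pathway map JSON"))
  tag <- function(a, b) sprintf("%s_vs_%s", a, b)
  ab <- comparative_map(map, ds, cond_a, cond_b, min_n = cfg$min_grid)
  paths <- list()
  write_bins <- function(cmp, t) {
    p <- file.path(d, sprintf("bins_%s.csv", t))
    utils::write.csv(cmp$bins, p, row.names = FALSE, quote = FALSE,
                     na = "NA")
    u <- file.path(d, sprintf("unmapped_%s.txt", t))
    writeLines(cmp$unmapped, u)
    rend <- render_map(cmp$styled, file.path(d, sprintf("map_%s", t)),
                       seed = cfg$seed)
    c(stats::setNames(list(p, u), paste0(c("bins_", "unmapped_"), t)),
      stats::setNames(rend, paste0(names(rend), "_", t)))
  }
  paths <- c(paths, write_bins(ab, tag(cond_a, cond_b)))
  out <- list(bins_ab = ab$bins)
  if (!is.null(cond_c)) {
    ac <- comparative_map(map, ds, cond_a, cond_c, min_n = cfg$min_grid)
    paths <- c(paths, write_bins(ac, tag(cond_a, cond_c)))
    vt <- variation_table(ab$bins, ac$bins)
    p <- file.path(d, "variation_table.csv")
    utils::write.csv(vt, p, row.names = FALSE)
    paths$variation <- p
    out$bins_ac <- ac$bins
    out$variation <- vt
  }
  paths$manifest <- write_manifest(
    cfg, "compare", list(profiles = cfg$profiles_csv, map = cfg$map_json),
    paths, d)
  c(out, list(paths = paths))
}

#' Run the full pipeline on synthetic data
#'
#' simulate -> classify -> correlate (control) -> map -> compare, then
#' scores the recovered structure against the planted truth.
#'
#' @param cfg A `run_config`. When `map_json` is unset a map is built from
#'   the simulated entities so the map stages still run.
#' @return List with the stage results and `scores` from [truth_check()].
#' @export
run_pipeline <- function(cfg) {
  sim <- run_simulate(cfg)
  cfg <- sim$config
  if (is.null(cfg$map_json)) {
    map <- synthetic_pathway_map(sim$dataset)
    cfg$map_json <- file.path(stage_dir(cfg, "simulate"),
                              "synthetic_map.json")
    write_pathway_map(map, cfg$map_json)
  }
  cls <- run_classify(cfg)
  control <- cfg$conditions[1L]
  corr <- run_correlate(cfg, control)
  mapped <- run_map(cfg, corr$met_assign, corr$gene_assign)
  cmp <- if (length(cfg$conditions) >= 3L)
    run_compare(cfg, control, cfg$conditions[2L], cfg$conditions[3L])
  else run_compare(cfg, control, cfg$conditions[2L])
  control_pat <- cls$patterns[cls$patterns$condition == control, ]
  scores <- truth_check(sim$truth, patterns = control_pat,
                        met_assign = corr$met_assign,
                        gene_assign = corr$gene_assign,
                        bins = cmp$bins_ab,
                        bin_condition = cfg$conditions[2L])
  list(simulate = sim, classify = cls, correlate = corr, map = mapped,
       compare = cmp, scores = scores, config = cfg)
}

#' Build a chain pathway map covering a dataset's entities
#'
#' A synthetic stand-in for a curated metabolic map, used so the mapping
#' stages can run on simulated data: metabolites become a chain of nodes
#' and genes are distributed over the connecting edges.
#'
#' @param d An `omics_dataset`.
#' @return A [pathway_map].
#' @export
synthetic_pathway_map <- function(d) {
  mets <- dataset_entities(d, kind = "metabolite")
  genes <- dataset_entities(d, kind = "gene")
  if (length(mets) < 2L)
    stop("need at least 2 metabolites to build a map", call. = FALSE)
  n_edges <- length(mets) - 1L
  gene_split <- split(genes, rep(seq_len(n_edges),
                                 length.out = length(genes)))
  nodes <- data.frame(id = mets, label = mets,
                      x = 60 * seq_along(mets),
                      y = 60 + 40 * (seq_along(mets) %% 2L),
                      stringsAsFactors = FALSE)
  nodes$compound_ids <- I(rep(list(character()), nrow(nodes)))
  edges <- data.frame(id = sprintf("e%02d", seq_len(n_edges)),
                      source = mets[-length(mets)], target = mets[-1L],
                      reversible = FALSE, stringsAsFactors = FALSE)
  edges$genes <- I(lapply(seq_len(n_edges), function(i)
    if (i <= length(gene_split)) gene_split[[i]] else character()))
  pathway_map(nodes, edges, name = "synthetic chain map")
}
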