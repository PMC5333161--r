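#' Canonical base shapes for synthetic time courses
#'
#' Unit-scale template shapes for the four planted temporal pattern
#' classes, on an arbitrary day grid:
#' \itemize{
#'   \item `increase`: logistic ramp rescaled to run 0.1 -> 1.0;
#'   \item `decrease`: its mirror, 1.0 -> 0.1;
#'   \item `variable`: a single-peak bump, rising from 0.1 to a peak at
#'     the grid midpoint and falling back to 0.1 (for an even number of
#'     points the two middle points share the maximum);
#'   \item `constant`: all 1.0.
#' }
#' On a uniformly spaced grid the ramp is odd about the grid midpoint and
#' the bump is even, so their Pearson correlation is exactly 0 -- which is
#' what makes `increase` and `variable` the default pair of planted
#' correlation blocks.
#'
#' @param kind One of `increase`, `decrease`, `variable`, `constant`.
#' @param grid Numeric day grid (length >= 3).
#' @param steepness Logistic steepness for the ramp (per day).
#' @return Numeric vector, one value per grid point.
#' @export
base_shape <- function(kind, grid, steepness = 1.5) {
  grid <- as.numeric(grid)
  if (length(grid) < 3L)
    stop("'grid' must have at least 3 points", call. = FALSE)
  kind <- match.arg(kind, c("increase", "decrease", "variable", "constant"))
  mid <- (min(grid) + max(grid)) / 2
  switch(kind,
    increase = {
      raw <- stats::plogis(steepness * (grid - mid))
      0.1 + 0.9 * (raw - min(raw)) / (max(raw) - min(raw))
    },
    decrease = 1.1 - base_shape("increase", grid, steepness),
    variable = {
      h <- 1 - abs(grid - mid) / (mid - min(grid))
      0.1 + 0.9 * h / max(h)
    },
    constant = rep(1, length(grid)))
}

#' Configuration for the synthetic time-course generator
#'
#' The defaults emulate the study design the analysis expects: daily
#' metabolite/culture sampling on days 0--5 and gene expression on days
#' 0--3, triplicate replicates, three lactate-dose conditions (0/5/10 mM)
#' where the dose perturbs profiles away from control, and two planted
#' correlation blocks built on mutually uncorrelated base shapes.
#'
#' @param n_metabolites,n_genes Entity counts (defaults 34 and 40).
#' @param met_times,gene_times Day grids (defaults 0:5 and 0:3).
#' @param n_replicates Replicates per time point (default 3).
#' @param noise_cv Relative SD of the multiplicative log-normal replicate
#'   noise (default 0.05).
#' @param block_shapes Named character vector: base shape per block id
#'   (default blocks `B1` = increase, `B2` = variable).
#' @param conditions data.frame with columns `label` and
#'   `perturbation_strength` in `[0, 1]` (0 = identical to control). The
#'   first row is the control. Defaults mimic 0/5/10 mM lactate with
#'   strengths 0, 0.3, 0.7.
#' @param affected Entities perturbed by non-control conditions:
#'   `"all"` (default) or a character vector of entity ids.
#' @param seed Mandatory integer seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_metabolites = 34L, n_genes = 40L,
                             met_times = 0:5, gene_times = 0:3,
                             n_replicates = 3L, noise_cv = 0.05,
                             block_shapes = c(B1 = "increase",
                                              B2 = "variable"),
                             conditions = data.frame(
                               label = c("0mM", "5mM", "10mM"),
                               perturbation_strength = c(0, 0.3, 0.7)),
                             affected = "all", seed) {
  if (missing(seed) || !is.finite(seed))
    stop("'seed' is mandatory", call. = FALSE)
  stopifnot(n_metabolites >= 2L, n_genes >= 2L, n_replicates >= 1L,
            noise_cv >= 0, length(block_shapes) >= 2L,
            !is.null(names(block_shapes)),
            all(conditions$perturbation_strength >= 0),
            all(conditions$perturbation_strength <= 1))
  if (conditions$perturbation_strength[1L] != 0)
    stop("the first condition is the control and must have strength 0",
         call. = FALSE)
  structure(list(n_metabolites = as.integer(n_metabolites),
                 n_genes = as.integer(n_genes),
                 met_times = as.numeric(met_times),
                 gene_times = as.numeric(gene_times),
                 n_replicates = as.integer(n_replicates),
                 noise_cv = noise_cv, block_shapes = block_shapes,
                 conditions = conditions, affected = affected,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# multiplicative log-normal noise factors with mean exactly 1, sd ~ cv
noise_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic multi-omics time-course dataset
#'
#' Entities are split round-robin between the planted blocks; every entity
#' in a block shares the block's base shape on its own grid (metabolite or
#' gene), scaled by a per-entity amplitude drawn log-uniformly from
#' [10, 1000], so within-block correlations are 1 and cross-block
#' correlations equal the cross-shape correlation (|r| <= 0.1 enforced)
#' before noise. A non-control condition with perturbation strength p
#' blends each affected entity's shape toward the other block's shape with
#' weight p, so the between-condition correlation with control decreases
#' monotonically in p. Replicate noise is multiplicative log-normal with
#' mean 1 and relative SD `noise_cv`. Three culture metrics echoing batch
#' culture are always added: `cell_number` (rise then fall, planted in the
#' bump block), `glucose` (monotone decrease, unblocked) and `lactate`
#' (monotone increase, planted in the ramp block).
#'
#' @param cfg A [synthetic_config()].
#' @return List with `dataset` (an `omics_dataset`) and `truth` (a
#'   data.frame of planted pattern, block and expected zero-noise display
#'   bin per condition).
#' @export
generate_synthetic <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  blocks <- names(cfg$block_shapes)
  # cross-block shape correlation check, on both grids
  for (grid in list(cfg$met_times, cfg$gene_times)) {
    shp <- lapply(cfg$block_shapes, base_shape, grid = grid)
    for (i in seq_along(shp)) for (j in seq_along(shp)) if (i < j) {
      r <- suppressWarnings(stats::cor(shp[[i]], shp[[j]]))
      if (is.finite(r) && abs(r) > 0.1)
        stop(sprintf(paste0("block shapes '%s' and '%s' correlate at ",
                            "r=%.3f (|r| > 0.1) on a configured grid; ",
                            "choose a different shape pairing"),
                     cfg$block_shapes[i], cfg$block_shapes[j], r),
             call. = FALSE)
    }
  }
  ids_met <- sprintf("MET%02d", seq_len(cfg$n_metabolites))
  ids_gene <- sprintf("Gene%02d", seq_len(cfg$n_genes))
  entity <- data.frame(
    entity_id = c(ids_met, ids_gene),
    kind = rep(c("metabolite", "gene"), c(cfg$n_metabolites, cfg$n_genes)),
    block = blocks[(seq_len(cfg$n_metabolites + cfg$n_genes) - 1L) %%
                     length(blocks) + 1L],
    stringsAsFactors = FALSE)
  # culture metrics: shapes echo batch culture; glucose's decrease shape is
  # anti-correlated with the ramp block so it stays outside the blocks
  entity <- rbind(entity, data.frame(
    entity_id = c("cell_number", "glucose", "lactate"),
    kind = "culture_metric",
    block = c(blocks[match("variable", cfg$block_shapes)],
              NA_character_,
              blocks[match("increase", cfg$block_shapes)]),
    stringsAsFactors = FALSE))
  shape_of <- function(ent) {
    if (ent$entity_id == "glucose") return("decrease")
    if (ent$entity_id == "cell_number") return("variable")
    if (ent$entity_id == "lactate") return("increase")
    unname(cfg$block_shapes[[ent$block]])
  }
  alt_shape_of <- function(shape) {
    # blend target: the first configured block shape that differs
    alt <- setdiff(unname(cfg$block_shapes), shape)
    if (length(alt)) alt[1L] else "variable"
  }
  units_of <- c(metabolite = "uM", gene = "FPKM", culture_metric = "mM")
  amplitudes <- stats::setNames(
    exp(stats::runif(nrow(entity), log(10), log(1000))), entity$entity_id)
  profiles <- list()
  truth_rows <- list()
  for (i in seq_len(nrow(entity))) {
    ent <- entity[i, ]
    grid <- if (ent$kind == "gene") cfg$gene_times else cfg$met_times
    shape <- shape_of(ent)
    base <- base_shape(shape, grid)
    alt <- base_shape(alt_shape_of(shape), grid)
    amp <- amplitudes[[ent$entity_id]]
    units <- if (ent$entity_id == "cell_number") "cells" else
      units_of[[ent$kind]]
    expected_bins <- character(nrow(cfg$conditions))
    for (ci in seq_len(nrow(cfg$conditions))) {
      p <- cfg$conditions$perturbation_strength[ci]
      is_affected <- identical(cfg$affected, "all") ||
        ent$entity_id %in% cfg$affected
      v <- if (is_affected) (1 - p) * base + p * alt else base
      expected_bins[ci] <- as.character(assign_bin(
        pearson_r(base, v, min_n = 3L)))
      reps <- lapply(seq_along(grid), function(t)
        amp * v[t] * noise_factors(cfg$n_replicates, cfg$noise_cv))
      profiles[[length(profiles) + 1L]] <- ts_profile(
        entity_id = ent$entity_id, entity_kind = ent$kind,
        condition = cfg$conditions$label[ci], times = grid,
        replicates = reps, units = units)
    }
    tr <- data.frame(entity_id = ent$entity_id, kind = ent$kind,
                     block = ent$block, pattern = shape,
                     stringsAsFactors = FALSE)
    for (ci in seq_len(nrow(cfg$conditions)))
      tr[[paste0("bin_", cfg$conditions$label[ci])]] <- expected_bins[ci]
    truth_rows[[length(truth_rows) + 1L]] <- tr
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  list(dataset = profile_dataset(profiles,
                                 metadata = list(seed = cfg$seed)),
       truth = truth)
}

#' Score recovered structure against the planted ground truth
#'
#' @param truth Ground-truth data.frame from [generate_synthetic()].
#' @param patterns Optional output of [classify_dataset()] for the control
#'   condition; scored as the fraction of entities whose recovered pattern
#'   equals the planted one.
#' @param met_assign,gene_assign Optional `cluster_assignment`s; scored as
#'   the adjusted Rand index between recovered A/B labels and planted
#'   blocks, over blocked entities of the axis kind (plus blocked culture
#'   metrics on the metabolite axis).
#' @param bins Optional bin table from [comparative_map()] with an
#'   attribute-free `bin` column, compared against the planted zero-noise
#'   bin of `bin_condition`.
#' @param bin_condition Condition label naming the `bin_<label>` truth
#'   column to score against.
#' @return List with `pattern_accuracy`, `ari` (named per axis, plus
#'   `mean`), and `bin_agreement`; elements are `NA` where the matching
#'   input was not supplied.
#' @export
truth_check <- function(truth, patterns = NULL, met_assign = NULL,
                        gene_assign = NULL, bins = NULL,
                        bin_condition = NULL) {
  out <- list(pattern_accuracy = NA_real_,
              ari = c(metabolite_axis = NA_real_, gene_axis = NA_real_,
                      mean = NA_real_),
              bin_agreement = NA_real_)
  if (!is.null(patterns)) {
    m <- match(truth$entity_id, patterns$entity_id)
    if (anyNA(m))
      stop("pattern table does not cover the ground-truth entities",
           call. = FALSE)
    out$pattern_accuracy <- mean(patterns$pattern[m] == truth$pattern)
  }
  axis_ari <- function(assign, kinds) {
    ids <- truth$entity_id[truth$kind %in% kinds & !is.na(truth$block)]
    ids <- intersect(ids, names(assign$labels))
    if (length(ids) < 2L)
      stop("cluster assignment does not cover the ground-truth entities",
           call. = FALSE)
    mclust::adjustedRandIndex(assign$labels[ids],
                              truth$block[match(ids, truth$entity_id)])
  }
  if (!is.null(met_assign))
    out$ari[["metabolite_axis"]] <- axis_ari(met_assign,
                                             c("metabolite",
                                               "culture_metric"))
  if (!is.null(gene_assign))
    out$ari[["gene_axis"]] <- axis_ari(gene_assign, "gene")
  out$ari[["mean"]] <- mean(out$ari[c("metabolite_axis", "gene_axis")],
                            na.rm = TRUE)
  if (!is.null(bins)) {
    if (is.null(bin_condition))
      stop("'bin_condition' is required to score bins", call. = FALSE)
    col <- paste0("bin_", bin_condition)
    if (!col %in% names(truth))
      stop(sprintf("no ground-truth bins for condition '%s'", bin_condition),
           call. = FALSE)
    common <- intersect(bins$entity_id, truth$entity_id)
    if (!length(common))
      stop("bin table does not cover the ground-truth entities",
           call. = FALSE)
    out$bin_agreement <- mean(
      bins$bin[match(common, bins$entity_id)] ==
        truth[[col]][match(common, truth$entity_id)])
  }
  out
}
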