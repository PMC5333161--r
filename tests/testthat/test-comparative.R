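test_that("assign_bin reproduces the five-bin display legend", {
  expect_equal(as.character(assign_bin(0.95)), "strong_pos")
  expect_equal(as.character(assign_bin(-0.7)), "strong_neg")
  expect_equal(as.character(assign_bin(0.25)), "weak_pos")
  # documented boundary closure: boundaries attach to the inner bin
  expect_equal(as.character(assign_bin(c(0.9, 0.5, 0, -0.5))),
               c("pos", "weak_pos", "weak_pos", "neg"))
  expect_equal(as.character(assign_bin(NA)), "na")
  expect_error(assign_bin(1.01), "\\[-1, 1\\]")

  # dense grid against the hand-written piecewise oracle, plus monotonicity
  grid <- seq(-1, 1, length.out = 2001)
  got <- assign_bin(grid)
  expect_equal(as.character(got), vapply(grid, oracle_bin, ""))
  ord <- c(strong_neg = 1, neg = 2, weak_pos = 3, pos = 4, strong_pos = 5)
  expect_true(all(diff(ord[as.character(got)]) >= 0))
})

test_that("between-condition correlation matches its definitional oracle", {
  d <- mk_dataset(
    mk_profile("A", c(1, 3, 7, 2), condition = "0mM"),
    mk_profile("A", c(1, 3, 7, 2), condition = "5mM"),
    mk_profile("A", c(-1, -3, -7, -2), condition = "10mM"))
  expect_equal(between_condition_r(d, "A", "0mM", "5mM"), 1.0)
  expect_equal(between_condition_r(d, "A", "0mM", "10mM"), -1.0)
  expect_error(between_condition_r(d, "B", "0mM", "5mM"), "no profile")
  set.seed(77)
  for (i in 1:10) {
    x <- stats::runif(6, 0, 50); y <- stats::runif(6, 0, 50)
    d2 <- mk_dataset(mk_profile("E", x), mk_profile("E", y,
                                                    condition = "5mM"))
    expect_equal(between_condition_r(d2, "E", "0mM", "5mM"),
                 oracle_pearson(x, y), tolerance = 1e-12)
  }
})

test_that("negating one condition flips strong positive to strong negative", {
  set.seed(12)
  for (i in 1:20) {
    x <- stats::runif(6, 1, 50)
    y <- x * stats::runif(6, 0.97, 1.03)   # keeps |r| > 0.9
    d <- mk_dataset(mk_profile("E", x), mk_profile("E", y,
                                                   condition = "5mM"),
                    mk_profile("E", -y, condition = "neg"))
    r <- between_condition_r(d, "E", "0mM", "5mM")
    if (!is.na(r) && r > 0.9) {
      expect_equal(between_condition_r(d, "E", "0mM", "neg"), -r)
      expect_equal(as.character(assign_bin(-r)), "strong_neg")
    }
  }
})

test_that("cluster styling follows the orange/light-blue/absent scheme", {
  map <- toy_map()
  met_asg <- structure(list(axis = "metabolite_axis",
                            labels = c(GLC = "A", PYR = "B"),
                            linkage = NULL, order = c("GLC", "PYR"), k = 2L),
                       class = "cluster_assignment")
  gene_asg <- structure(list(axis = "gene_axis",
                             labels = c(Gapdh = "A", Pgk = "A", Ldha = "B"),
                             linkage = NULL, order = c("Gapdh", "Pgk",
                                                       "Ldha"), k = 2L),
                        class = "cluster_assignment")
  pal <- map_palette()
  sm <- style_by_cluster(map, met_asg, gene_asg)
  expect_equal(sm$node_styles$fill[sm$node_styles$node_id == "GLC"],
               unname(pal[["orange"]]))
  expect_equal(sm$node_styles$fill[sm$node_styles$node_id == "PYR"],
               unname(pal[["lightblue"]]))
  # metabolite not measured -> white node
  expect_equal(sm$node_styles$fill[sm$node_styles$node_id == "LAC"],
               unname(pal[["white"]]))
  expect_equal(sm$edge_styles$stroke[sm$edge_styles$edge_id == "e1"],
               unname(pal[["orange"]]))
  expect_equal(sm$edge_styles$stroke[sm$edge_styles$edge_id == "e2"],
               unname(pal[["lightblue"]]))
  # genes in conflicting clusters -> grey edge plus logged conflict
  gene_conf <- gene_asg
  gene_conf$labels <- c(Gapdh = "A", Pgk = "B", Ldha = "B")
  expect_warning(sm2 <- style_by_cluster(map, met_asg, gene_conf),
                 "conflicting")
  expect_equal(sm2$edge_styles$stroke[sm2$edge_styles$edge_id == "e1"],
               unname(pal[["grey"]]))
})

test_that("self-comparison maps every non-constant entity to strong_pos", {
  sim <- generate_synthetic(synthetic_config(n_metabolites = 6L,
                                             n_genes = 6L, noise_cv = 0.05,
                                             seed = 21L))
  map <- synthetic_pathway_map(sim$dataset)
  cmp <- comparative_map(map, sim$dataset, "0mM", "0mM")
  measured <- cmp$bins[cmp$bins$entity_id %in%
                         dataset_entities(sim$dataset), ]
  expect_true(all(measured$bin == "strong_pos"))
  # a constant profile gives the na bin and absent styling
  d <- mk_dataset(mk_profile("GLC", c(5, 5, 5, 5)),
                  mk_profile("GLC", c(5, 5, 5, 5), condition = "5mM"),
                  mk_profile("PYR", c(1, 2, 3, 4)),
                  mk_profile("PYR", c(1, 2, 3, 4), condition = "5mM"))
  cmp2 <- comparative_map(toy_map(), d, "0mM", "5mM")
  expect_equal(cmp2$bins$bin[cmp2$bins$entity_id == "GLC"], "na")
  expect_equal(cmp2$styled$node_styles$fill[
    cmp2$styled$node_styles$node_id == "GLC"],
    unname(map_palette()[["white"]]))
  expect_equal(cmp2$bins$bin[cmp2$bins$entity_id == "PYR"], "strong_pos")
  # strong bins enlarge nodes
  expect_gt(cmp2$styled$node_styles$size[
    cmp2$styled$node_styles$node_id == "PYR"],
    cmp2$styled$node_styles$size[cmp2$styled$node_styles$node_id == "GLC"])
})

test_that("multi-gene edges take the most extreme gene and report unmapped", {
  # Gapdh strongly inverted, Pgk mildly positive -> edge e1 is strong_neg
  d <- mk_dataset(
    mk_profile("Gapdh", c(1, 2, 3, 4), kind = "gene", units = "FPKM"),
    mk_profile("Gapdh", c(4, 3, 2, 1), kind = "gene", units = "FPKM",
               condition = "5mM"),
    mk_profile("Pgk", c(1, 2, 3, 4), kind = "gene", units = "FPKM"),
    mk_profile("Pgk", c(1, 2.4, 2.6, 4), kind = "gene", units = "FPKM",
               condition = "5mM"),
    mk_profile("Offmap", c(1, 2, 3), kind = "gene", units = "FPKM"),
    mk_profile("Offmap", c(1, 2, 3), kind = "gene", units = "FPKM",
               condition = "5mM"))
  cmp <- comparative_map(toy_map(), d, "0mM", "5mM")
  e1 <- cmp$styled$edge_styles[cmp$styled$edge_styles$edge_id == "e1", ]
  expect_equal(e1$stroke, unname(map_palette()[["blue"]]))
  expect_equal(e1$width, 5)  # bold: 2 * 2.5
  # gene absent from the dataset -> grey edge
  e2 <- cmp$styled$edge_styles[cmp$styled$edge_styles$edge_id == "e2", ]
  expect_equal(e2$stroke, unname(map_palette()[["grey"]]))
  expect_equal(cmp$unmapped, "Offmap")
})

test_that("the variation table groups entities by colour transition", {
  bins_ab <- data.frame(entity_id = c("PYR", "AKG", "Gls"),
                        kind = c("metabolite", "metabolite", "gene"),
                        r = c(0.8, 0.8, 0.6),
                        bin = c("pos", "pos", "pos"),
                        stringsAsFactors = FALSE)
  bins_ac <- data.frame(entity_id = c("PYR", "AKG", "Gls"),
                        kind = c("metabolite", "metabolite", "gene"),
                        r = c(0.2, 0.3, 0.95),
                        bin = c("weak_pos", "weak_pos", "strong_pos"),
                        stringsAsFactors = FALSE)
  vt <- variation_table(bins_ab, bins_ac)
  rg <- vt[vt$pattern == "red/green" & vt$kind == "metabolite", ]
  expect_equal(rg$n, 2L)
  expect_equal(rg$entities, "AKG,PYR")
  expect_equal(vt$pattern[vt$kind == "gene"], "red/bold_red")
  # identical bins -> single unchanged group, full coverage
  vt2 <- variation_table(bins_ab, bins_ab)
  expect_equal(sum(vt2$n), 3L)
  expect_true(all(vt2$pattern %in% c("red/red")))
  expect_error(variation_table(bins_ab, bins_ac[1:2, ]), "same entities")
})

test_that("cluster gene lists export sorted and only from the gene axis", {
  asg <- structure(list(axis = "gene_axis",
                        labels = c(Ldha = "A", Cs = "A", Pgk = "B",
                                   cell_number = "A"),
                        linkage = NULL, order = NULL, k = 2L),
                   class = "cluster_assignment")
  f <- tempfile()
  export_cluster_gene_list(asg, "A", f, exclude = "cell_number")
  expect_equal(readLines(f), c("Cs", "Ldha"))
  export_cluster_gene_list(asg, "B", f)
  expect_equal(readLines(f), "Pgk")
  met <- asg; met$axis <- "metabolite_axis"
  expect_error(export_cluster_gene_list(met, "A", f), "gene-axis")
  expect_error(export_cluster_gene_list(asg, "Q", f), "unknown cluster")
})
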