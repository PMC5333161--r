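test_that("base shapes have the planted geometry", {
  for (grid in list(0:5, 0:3, 0:6)) {
    inc <- base_shape("increase", grid)
    expect_true(all(diff(inc) >= 0))
    expect_equal(range(inc), c(0.1, 1.0))
    dec <- base_shape("decrease", grid)
    expect_equal(dec, rev(inc))
    expect_equal(base_shape("constant", grid), rep(1, length(grid)))
    bump <- base_shape("variable", grid)
    peak <- which.max(bump)
    expect_gt(peak, 1L)
    expect_lt(peak, length(grid))
    # the ramp is odd and the bump even about the grid midpoint, so the
    # default block shapes are exactly uncorrelated
    expect_equal(stats::cor(inc, bump), 0, tolerance = 1e-12)
  }
  expect_error(base_shape("increase", 0:1), "at least 3")
  expect_error(base_shape("wiggle", 0:5), "arg")
})

test_that("generation is reproducible and respects the planted structure", {
  cfg <- synthetic_config(n_metabolites = 6L, n_genes = 6L, seed = 33L)
  a <- generate_synthetic(cfg)
  b <- generate_synthetic(cfg)
  expect_identical(a$dataset, b$dataset)
  expect_identical(a$truth, b$truth)
  expect_error(synthetic_config(n_metabolites = 4L, n_genes = 4L),
               "seed")

  # zero noise, zero perturbation: every entity correlates 1 with control
  z <- generate_synthetic(synthetic_config(
    n_metabolites = 5L, n_genes = 5L, noise_cv = 0,
    conditions = data.frame(label = c("0mM", "same"),
                            perturbation_strength = c(0, 0)), seed = 2L))
  for (id in dataset_entities(z$dataset))
    expect_equal(between_condition_r(z$dataset, id, "0mM", "same"), 1.0)

  # zero noise: same-block entities correlate exactly 1 within a set
  cm <- correlation_matrix(generate_synthetic(synthetic_config(
    n_metabolites = 6L, n_genes = 4L, noise_cv = 0,
    seed = 4L))$dataset, "0mM", rows = "metabolite")
  expect_equal(cm["MET01", "MET03"], 1.0, tolerance = 1e-12)
  expect_equal(cm["MET02", "MET04"], 1.0, tolerance = 1e-12)
  expect_lt(abs(cm["MET01", "MET02"]), 0.1 + 1e-9)

  # an anti-correlated block pairing is rejected with guidance
  expect_error(generate_synthetic(synthetic_config(
    n_metabolites = 4L, n_genes = 4L,
    block_shapes = c(B1 = "increase", B2 = "decrease"), seed = 1L)),
    "different shape pairing")
})

test_that("zero-noise recovery of pattern, blocks and bins is exact", {
  sim <- generate_synthetic(synthetic_config(n_metabolites = 10L,
                                             n_genes = 10L, noise_cv = 0,
                                             seed = 8L))
  pat <- subset(classify_dataset(sim$dataset), condition == "0mM")
  cm_met <- correlation_matrix(sim$dataset, "0mM", rows = "metabolite",
                               include_culture = TRUE)
  cm_gene <- correlation_matrix(sim$dataset, "0mM", rows = "gene",
                                include_culture = TRUE)
  met_asg <- two_largest_clusters(hierarchical_cluster(
    suppressWarnings(correlation_profile_features(cm_met))), k = 3,
    axis = "metabolite_axis")
  gene_asg <- two_largest_clusters(hierarchical_cluster(
    suppressWarnings(correlation_profile_features(cm_gene))), k = 3,
    axis = "gene_axis")
  map <- synthetic_pathway_map(sim$dataset)
  cmp <- comparative_map(map, sim$dataset, "0mM", "5mM")
  scores <- truth_check(sim$truth, patterns = pat, met_assign = met_asg,
                        gene_assign = gene_asg, bins = cmp$bins,
                        bin_condition = "5mM")
  expect_equal(scores$pattern_accuracy, 1.0)
  expect_equal(scores$ari[["metabolite_axis"]], 1.0)
  expect_equal(scores$ari[["gene_axis"]], 1.0)
  expect_equal(scores$bin_agreement, 1.0)
})

test_that("cluster recovery is robust to 5% replicate noise", {
  ok <- 0L
  for (seed in 1:20) {
    sim <- generate_synthetic(synthetic_config(n_metabolites = 15L,
                                               n_genes = 15L,
                                               noise_cv = 0.05,
                                               seed = seed))
    cm <- correlation_matrix(sim$dataset, "0mM", rows = "metabolite",
                             include_culture = TRUE)
    asg <- two_largest_clusters(hierarchical_cluster(
      suppressWarnings(correlation_profile_features(cm))), k = 3,
      axis = "metabolite_axis")
    ari <- truth_check(sim$truth, met_assign = asg)$ari[["metabolite_axis"]]
    if (ari >= 0.9) ok <- ok + 1L
  }
  expect_gte(ok, 19L)
})

test_that("stronger dose perturbations lower between-condition correlation", {
  for (seed in 1:20) {
    sim <- generate_synthetic(synthetic_config(
      n_metabolites = 8L, n_genes = 8L, noise_cv = 0.05,
      conditions = data.frame(label = c("0mM", "5mM", "10mM"),
                              perturbation_strength = c(0, 0.3, 0.7)),
      seed = 100L + seed))
    ids <- dataset_entities(sim$dataset, kind = c("metabolite", "gene"))
    r_weak <- vapply(ids, function(id)
      between_condition_r(sim$dataset, id, "0mM", "5mM"), 0)
    r_strong <- vapply(ids, function(id)
      between_condition_r(sim$dataset, id, "0mM", "10mM"), 0)
    expect_gte(mean(r_weak, na.rm = TRUE), mean(r_strong, na.rm = TRUE))
    # the strong-positive count can only shrink with dose
    expect_gte(sum(assign_bin(r_weak) == "strong_pos"),
               sum(assign_bin(r_strong) == "strong_pos"))
  }
})

test_that("truth_check scores perfectly on truth and near zero on shuffles", {
  sim <- generate_synthetic(synthetic_config(n_metabolites = 25L,
                                             n_genes = 25L, noise_cv = 0,
                                             seed = 13L))
  truth <- sim$truth
  perfect <- truth_check(
    truth,
    patterns = data.frame(entity_id = truth$entity_id,
                          pattern = truth$pattern),
    met_assign = structure(list(
      axis = "metabolite_axis",
      labels = stats::setNames(
        ifelse(truth$block == "B1", "A", "B"),
        truth$entity_id)[truth$kind != "gene" & !is.na(truth$block)]),
      class = "cluster_assignment"),
    bins = data.frame(entity_id = truth$entity_id,
                      bin = truth$bin_5mM),
    bin_condition = "5mM")
  expect_equal(perfect$pattern_accuracy, 1.0)
  expect_equal(perfect$ari[["metabolite_axis"]], 1.0)
  expect_equal(perfect$bin_agreement, 1.0)

  # random labels over two balanced blocks: mean |ARI| below 0.05
  blocked <- truth$entity_id[truth$kind == "metabolite"]
  planted <- truth$block[match(blocked, truth$entity_id)]
  set.seed(99)
  aris <- replicate(1000, {
    mclust::adjustedRandIndex(sample(rep(c("A", "B"),
                                         length.out = length(blocked))),
                              planted)
  })
  expect_lt(mean(abs(aris)), 0.05)

  expect_error(truth_check(truth,
                           patterns = data.frame(entity_id = "nope",
                                                 pattern = "constant")),
               "cover")
})
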