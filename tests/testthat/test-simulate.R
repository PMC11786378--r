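test_that("sim_config rejects invalid fields by name", {
  expect_error(sim_config(seed = 1.5), "seed", class = "gd_invalid_config")
  expect_error(sim_config(group_fractions = c(epigene = 0.5,
                                              non_epigene = 0.6,
                                              histone = 0.1)),
               "group_fractions", class = "gd_invalid_config")
  expect_error(sim_config(dirichlet_base_concentration = 0),
               "dirichlet_base_concentration", class = "gd_invalid_config")
  expect_error(sim_config(between_tissue_concentration = -1),
               "between_tissue_concentration", class = "gd_invalid_config")
  expect_error(sim_config(trajectory_params = list(
    class_mix = c(increasing = 1, decreasing = 0, oscillating = 0, flat = 0),
    noise_sd = -0.1, n_subregions = 2, ages = c(8, 12, 16, 20, 24))),
    "noise_sd", class = "gd_invalid_config")
})

test_that("every generator is bit-identical under a fixed seed", {
  cfg <- sim_config(seed = 60, n_genes = 15, n_tissues = 4)
  expect_identical(gen_annotation(cfg), gen_annotation(cfg))
  expect_identical(gen_isoform_tensor(cfg), gen_isoform_tensor(cfg))
  expect_identical(gen_complex_table(cfg), gen_complex_table(cfg))
  expect_identical(gen_disorder_table(cfg), gen_disorder_table(cfg))
  ont <- gen_ontology(cfg)
  expect_identical(gen_disease_annotations(cfg, ont),
                   gen_disease_annotations(cfg, ont))
  expect_identical(gen_temporal_profiles(cfg), gen_temporal_profiles(cfg))
})

test_that("planted group length shift shows in sample geometric means", {
  cfg <- sim_config(seed = 61, n_genes = 2000,
                    group_fractions = c(epigene = 0.5, non_epigene = 0.5,
                                        histone = 0))
  ann <- gen_annotation(cfg)
  feats <- structure_features(ann)
  gm <- tapply(feats$gene_length, feats$group,
               function(v) as.numeric(geometric_mean(v)))
  expect_gt(gm[["epigene"]], gm[["non_epigene"]])
})

test_that("tensor generation respects its concentration and tree contracts", {
  # infinite-concentration limit: tissue profiles collapse onto the base
  cfg <- sim_config(seed = 62, n_genes = 12, n_tissues = 4,
                    between_tissue_concentration = 1e6)
  sim <- gen_isoform_tensor(cfg)
  for (g in names(sim$tensor$genes)) {
    tx <- sim$tensor$genes[[g]]
    if (length(tx) < 2) next
    props <- apply(sim$tensor$abund[tx, , drop = FALSE], 2,
                   function(x) x / sum(x))
    expect_lt(max(abs(props - sim$truth$base_profiles[[g]])), 1e-2)
  }
  # single-isoform genes have proportion exactly 1 everywhere
  singles <- names(sim$tensor$genes)[lengths(sim$tensor$genes) == 1]
  for (g in singles) {
    tot <- colSums(sim$tensor$abund[sim$tensor$genes[[g]], , drop = FALSE])
    expect_true(all(sim$tensor$abund[sim$tensor$genes[[g]], ] / tot == 1))
  }
  # leaf-count mismatch is rejected
  bad <- sim_config(seed = 1, n_genes = 5, n_tissues = 5,
                    tree_spec = "((T1:1,T2:1):1,(T3:1,T4:1):1);")
  expect_error(gen_isoform_tensor(bad), "leaves",
               class = "gd_invalid_config")
  # abundances are non-negative and the tree matches the spec
  expect_true(all(sim$tensor$abund >= 0))
  expect_equal(sort(sim$tree$tip.label), paste0("T", 1:4))
})

test_that("complex generator covers the single-complex edge case", {
  cfg <- sim_config(seed = 63, n_genes = 50,
                    complex_params = list(constitutive_size = 2L,
                                          variable_pool_size = 3L,
                                          prob_in_complex = 1, prob_multi = 0))
  tab <- gen_complex_table(cfg, sprintf("g%02d", 1:50), rep("epigene", 50))
  truth <- attr(tab, "truth")
  expect_true(all(truth$n_complexes == 1))
  expect_true(all(is.na(truth$n_variable))) # excluded from the statistic
  for (g in truth$gene_id) {
    expect_error(variable_partners(tab, g), class = "gd_excluded_input")
  }
})

test_that("disease generator plants filterable flags; ontology maps paths", {
  cfg <- sim_config(seed = 64, n_genes = 80)
  ont <- gen_ontology(cfg)
  expect_length(major_systems(ont$graph), 11)
  # single-path mapping: every generated term maps to its recorded system
  for (t in setdiff(names(ont$term_system), "XP:MULTI.L1")) {
    expect_equal(map_terms_to_systems(ont$graph, t),
                 sort(unique(ont$term_system[[t]])))
  }
  ann <- gen_disease_annotations(cfg, ont)
  truth <- attr(ann, "truth")
  # flagged rows are present in the raw table but marked for filtering
  expect_true(any(ann$somatic | ann$susceptibility))
  expect_equal(truth$retained, !ann$somatic & !ann$susceptibility)
})

test_that("flat trajectories with zero noise have zero temporal range", {
  cfg <- sim_config(seed = 65, n_genes = 12,
                    trajectory_params = list(
                      class_mix = c(increasing = 0, decreasing = 0,
                                    oscillating = 0, flat = 1),
                      noise_sd = 0, n_subregions = 2,
                      ages = seq(8, 40, by = 8)))
  sim <- gen_temporal_profiles(cfg)
  profs <- prepare_profiles(sim$samples)
  for (p in profs) {
    rng <- apply(p$mat, 1, function(x) max(x) - min(x))
    expect_true(all(rng < 1e-9))
    expect_equal(nrow(filter_by_range(p, 0.5)$mat), 0)
  }
})
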