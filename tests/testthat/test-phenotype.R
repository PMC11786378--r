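test_that("ontology_graph validates rootedness and acyclicity", {
  g <- toy_ontology()
  expect_setequal(g$terms, c("root", "sysA", "sysB", "A1", "A1.1", "B1", "XM"))
  expect_error(
    ontology_graph(data.frame(child = c("a", "b"), parent = c("b", "a"))),
    class = "gd_invalid_input") # cycle
  expect_error(
    ontology_graph(data.frame(child = c("a", "c"), parent = c("r1", "r2"))),
    class = "gd_invalid_input") # two roots
})

test_that("major_systems are exactly the root's direct children", {
  expect_setequal(major_systems(toy_ontology()), c("sysA", "sysB"))
  chain <- ontology_graph(data.frame(child = c("B", "A"),
                                     parent = c("A", "root")))
  expect_equal(major_systems(chain), "A")
  cfg <- sim_config(seed = 1, n_genes = 5)
  ont <- gen_ontology(cfg)
  expect_length(major_systems(ont$graph), 11)
})

test_that("map_terms_to_systems closes over ancestors", {
  g <- toy_ontology()
  expect_equal(map_terms_to_systems(g, "sysA"), "sysA") # self-inclusion
  expect_equal(map_terms_to_systems(g, "A1.1"), "sysA") # two levels up
  expect_equal(map_terms_to_systems(g, "B1"), "sysB")
  expect_setequal(map_terms_to_systems(g, c("A1.1", "B1")),
                  c("sysA", "sysB"))
  expect_error(map_terms_to_systems(g, "nope"), "nope",
               class = "gd_invalid_input")

  # multi-parent DAG: a term under two systems maps to both
  dag <- ontology_graph(data.frame(
    child  = c("sysA", "sysB", "dual", "dual"),
    parent = c("root", "root", "sysA", "sysB")))
  expect_setequal(map_terms_to_systems(dag, "dual"), c("sysA", "sysB"))
  expect_true(all(map_terms_to_systems(dag, c("dual", "sysA")) %in%
                    major_systems(dag)))
})

test_that("filter_diseases drops somatic and susceptibility records", {
  ann <- data.frame(gene_id = paste0("g", 1:4), disease_id = paste0("d", 1:4),
                    modes = "Autosomal dominant",
                    somatic = c(FALSE, TRUE, FALSE, FALSE),
                    susceptibility = c(FALSE, FALSE, TRUE, FALSE),
                    terms = "A1")
  out <- filter_diseases(ann)
  expect_equal(out$gene_id, c("g1", "g4"))
  expect_equal(attr(out, "n_somatic_removed"), 1)
  expect_equal(attr(out, "n_susceptibility_removed"), 1)
  clean <- ann[c(1, 4), ]
  expect_equal(filter_diseases(clean)$gene_id, clean$gene_id)
  allsom <- transform(ann, somatic = TRUE)
  expect_equal(nrow(filter_diseases(allsom)), 0)

  # generator ground truth: retained rows are exactly the unflagged rows
  cfg <- sim_config(seed = 40, n_genes = 150,
                    disease_params = list(
                      prob_disease = c(epigene = 1, non_epigene = 1,
                                       histone = 1),
                      prob_somatic = 0.15, prob_susceptibility = 0.05,
                      prob_dominant = c(epigene = 0.68, non_epigene = 0.45,
                                        histone = 0.45),
                      max_diseases = 2L, max_terms = 3L))
  ont <- gen_ontology(cfg)
  sim <- gen_disease_annotations(cfg, ont)
  kept <- filter_diseases(sim)
  expect_equal(nrow(kept), sum(attr(sim, "truth")$retained))
})

test_that("systems_per_gene unions over diseases and stays within systems", {
  g <- toy_ontology()
  ann <- data.frame(
    gene_id = c("g1", "g2", "g2"), disease_id = c("d1", "d2", "d3"),
    modes = "Autosomal dominant", somatic = FALSE, susceptibility = FALSE,
    terms = c("A1.1;B1", "A1", "A1.1"))
  out <- systems_per_gene(g, ann)
  expect_equal(out$n_systems[out$gene_id == "g1"], 2) # one disease, 2 systems
  expect_equal(out$n_systems[out$gene_id == "g2"], 1) # two diseases, same sys
  # monotone under added diseases
  more <- rbind(ann, data.frame(gene_id = "g2", disease_id = "d4",
                                modes = "Autosomal recessive", somatic = FALSE,
                                susceptibility = FALSE, terms = "B1"))
  out2 <- systems_per_gene(g, more)
  expect_gte(out2$n_systems[out2$gene_id == "g2"],
             out$n_systems[out$gene_id == "g2"])
  # genes without diseases are absent
  expect_false("g3" %in% out$gene_id)
  # generator ground-truth system sets recovered through the module path
  cfg <- sim_config(seed = 41, n_genes = 60)
  ont <- gen_ontology(cfg)
  sim <- gen_disease_annotations(cfg, ont)
  kept <- filter_diseases(sim)
  got <- systems_per_gene(ont$graph, kept)
  truth <- attr(sim, "truth")$systems_per_gene
  for (i in seq_len(nrow(got))) {
    expect_equal(strsplit(got$systems[i], ";")[[1]],
                 truth[[got$gene_id[i]]])
  }
})

test_that("inheritance_summary ORs normalized modes per gene", {
  ann <- data.frame(
    gene_id = c("g1", "g2", "g2", "g3"),
    disease_id = paste0("d", 1:4),
    modes = c("Autosomal dominant", "autosomal DOMINANT;X-linked recessive",
              "Autosomal recessive", "Multifactorial"),
    somatic = FALSE, susceptibility = FALSE, terms = "A1")
  out <- inheritance_summary(ann)
  expect_equal(out$any_dominant, c(TRUE, TRUE, FALSE))
  expect_equal(out$any_recessive, c(FALSE, TRUE, FALSE))
  expect_warning(inheritance_summary(
    transform(ann[1, ], modes = "weird-mode")), "other")
})
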