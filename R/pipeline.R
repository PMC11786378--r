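# End-to-end orchestration: validate a JSON config, run every stage (from
# files or from the synthetic generators), assemble the group-comparison
# summary table and a reproducibility manifest.

pipeline_known_keys <- c("seed", "out_dir", "simulate", "inputs", "stats",
                         "thresholds", "groups")

#' Validate a pipeline configuration
#'
#' Accepts a JSON file path or a list. Unknown keys are rejected by name;
#' referenced input paths must exist; seeds must be integers. Missing
#' sections fall back to documented defaults (synthetic inputs, n_perm
#' 1000).
#'
#' @param config path to a JSON config or a list.
#' @return validated `pipeline_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    check_that(file.exists(config), paste("config file not found:", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  check_that(is.list(config), "config must be a list or a JSON file path")
  unknown <- setdiff(names(config), pipeline_known_keys)
  check_that(length(unknown) == 0,
             paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  config$seed <- config$seed %||% 1L
  check_that(is.numeric(config$seed) && config$seed == round(config$seed),
             "seed must be an integer")
  config$stats <- utils::modifyList(
    list(n_perm = 1000L, sided = "two",
         focal = "epigene", contrast = "non_epigene"),
    config$stats %||% list())
  config$thresholds <- utils::modifyList(
    list(min_timepoints = 5, max_age = 40, range_min = 0.5,
         assign_threshold = 0.8, cut = 0.2),
    config$thresholds %||% list())
  for (p in unlist(config$inputs)) {
    check_that(file.exists(p), paste("input path does not exist:", p))
  }
  sim_args <- config$simulate %||% list()
  sim_args$seed <- sim_args$seed %||% config$seed
  config$sim_config <- do.call(sim_config, sim_args)
  structure(config, class = "pipeline_config")
}

summary_feature <- function(df, value_col, labels, cfgst, agg) {
  merged <- merge(df, labels, by = "gene_id")
  merged <- merged[!is.na(merged[[value_col]]) &
                     merged$group %in% c(cfgst$focal, cfgst$contrast), ]
  groups <- split(merged[[value_col]], merged$group)
  if (length(groups[[cfgst$focal]]) < 2 ||
      length(groups[[cfgst$contrast]]) < length(groups[[cfgst$focal]])) {
    return(data.frame(feature = value_col, statistic = agg,
                      focal_value = NA_real_, contrast_value = NA_real_,
                      p_value = NA_real_, saturated = NA,
                      stringsAsFactors = FALSE))
  }
  fn <- stat_aggregators()[[agg]]
  pt <- permutation_test(merged[[value_col]], merged$group,
                         focal = cfgst$focal, statistic = agg,
                         n_perm = cfgst$n_perm, sided = cfgst$sided,
                         keep_null = FALSE)
  data.frame(feature = value_col, statistic = agg,
             focal_value = fn(groups[[cfgst$focal]]),
             contrast_value = fn(groups[[cfgst$contrast]]),
             p_value = pt$p_two_sided, saturated = pt$saturated,
             stringsAsFactors = FALSE)
}

#' Run the full comparison pipeline
#'
#' Executes the ten stages (simulate or load, structure, weights, diversity,
#' complexes, disorder, phenotype, specificity, temporal, summary) and
#' produces the group-comparison table: for each per-gene feature, the
#' focal/contrast group summaries and a permutation-test p-value. All
#' randomness is seeded from the config; rerunning with the same config
#' yields identical tables.
#'
#' @param config a `pipeline_config` (see [validate_config]) or anything it
#'   accepts.
#' @return list with per-stage tables, the `summary` data.frame and a
#'   `manifest` (stages, seed, parameters).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  cfg <- config$sim_config
  inputs <- config$inputs %||% list()
  stages <- character(0)
  run_stage <- function(name, expr) {
    stages <<- c(stages, name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  annotation <- run_stage("simulate", {
    if (!is.null(inputs$annotation_tsv)) read_annotation_tsv(inputs$annotation_tsv)
    else gen_annotation(cfg)
  })
  labels <- data.frame(gene_id = annotation$genes$gene_id,
                       group = annotation$genes$group,
                       stringsAsFactors = FALSE)

  feats <- run_stage("structure", structure_features(annotation))

  sim_tensor <- NULL
  tensor <- if (!is.null(inputs$matrix)) {
    read_isoform_matrix(inputs$matrix, inputs$map)
  } else {
    sim_tensor <- gen_isoform_tensor(cfg, annotation)
    sim_tensor$tensor
  }
  tree <- if (!is.null(inputs$tree)) read_sample_tree(inputs$tree)
          else if (!is.null(sim_tensor)) sim_tensor$tree else NULL

  weights_tab <- run_stage("weights", {
    w_sim <- if (!is.null(tree)) similarity_weights(tree) else {
      tr <- cluster_samples(tensor$abund)
      tree <<- tr
      similarity_weights(tr)
    }
    data.frame(sample = names(w_sim), similarity = as.numeric(w_sim),
               stringsAsFactors = FALSE)
  })

  diversity <- run_stage("diversity", {
    d <- diversity_table(tensor, tree)
    names(d)[names(d) == "mean_entropy_bits"] <- "mean_entropy"
    names(d)[names(d) == "mean_divergence_bits"] <- "mean_divergence"
    d
  })

  cx <- run_stage("complexes", {
    tab <- if (!is.null(inputs$complexes)) read_complex_table(inputs$complexes)
           else gen_complex_table(cfg, labels$gene_id, labels$group)
    complex_summary(tab, labels)$genes
  })

  dis <- run_stage("disorder", {
    tab <- if (!is.null(inputs$disorder)) read_disorder_table(inputs$disorder)
           else gen_disorder_table(cfg, labels$gene_id, labels$group)
    st <- disorder_stats(tab)
    names(st)[names(st) == "protein_id"] <- "gene_id"
    st
  })

  phen <- run_stage("phenotype", {
    graph <- if (!is.null(inputs$ontology_edges))
      read_ontology_edges(inputs$ontology_edges) else gen_ontology(cfg)$graph
    ann <- if (!is.null(inputs$disease_annotations))
      read_disease_annotations(inputs$disease_annotations)
    else gen_disease_annotations(cfg, gen_ontology(cfg),
                                 labels$gene_id, labels$group)
    systems_per_gene(graph, filter_diseases(ann))
  })

  spec_tab <- run_stage("specificity", {
    gene_tpm <- t(vapply(tensor$genes, function(tx)
      colSums(tensor$abund[tx, , drop = FALSE]),
      numeric(ncol(tensor$abund))))
    eps <- median_normalize(log_transform(as_expr_matrix(gene_tpm, "tpm")))
    w_sim <- stats::setNames(weights_tab$similarity, weights_tab$sample)
    specificity_table(unclass(eps), w_sim)
  })

  temporal <- run_stage("temporal", {
    samples <- if (!is.null(inputs$temporal)) read_temporal_long(inputs$temporal)
               else gen_temporal_profiles(cfg)$samples
    th <- config$thresholds
    profiles <- prepare_profiles(samples, th$min_timepoints, th$max_age)
    seed_genes <- labels$gene_id[labels$group == config$stats$focal]
    if (length(intersect(seed_genes, unique(samples$gene))) < 2) {
      seed_genes <- unique(samples$gene) # fall back: cluster everything
    }
    sets <- lapply(profiles, function(p) {
      p <- scale_max(filter_by_range(p, th$range_min))
      cs <- cluster_seed_genes(p, seed_genes, cut = th$cut)
      assign_genes(cs, p, threshold = th$assign_threshold)
    })
    if (length(sets) >= 1 &&
        sum(vapply(sets, function(s) nrow(s$means), integer(1))) >= 2) {
      meta <- metacluster(sets, cut = th$cut)
    } else meta <- NULL
    list(cluster_sets = sets, metaclusters = meta)
  })

  summary <- run_stage("summary", {
    cfgst <- config$stats
    per_gene <- Reduce(function(a, b) merge(a, b, by = "gene_id", all = TRUE),
                       list(feats[c("gene_id", "gene_length",
                                    "transcript_length", "n_isoforms")],
                            diversity[c("gene_id", "mean_entropy",
                                        "mean_divergence")],
                            cx[c("gene_id", "n_complexes",
                                 "n_variable_partners")],
                            dis[c("gene_id", "disordered_fraction",
                                  "max_disordered_length")],
                            phen[c("gene_id", "n_systems")],
                            spec_tab))
    specs <- list(
      c("gene_length", "geometric_mean"),
      c("transcript_length", "geometric_mean"),
      c("n_isoforms", "geometric_mean"),
      c("mean_entropy", "mean"),
      c("mean_divergence", "mean"),
      c("n_complexes", "mean"),
      c("n_variable_partners", "geometric_mean"),
      c("disordered_fraction", "mean"),
      c("max_disordered_length", "median"),
      c("n_systems", "mean"),
      c("tau", "mean"))
    set.seed(config$seed)
    out <- do.call(rbind, lapply(specs, function(sp)
      summary_feature(per_gene, sp[1], labels, cfgst, sp[2])))
    rownames(out) <- NULL
    out
  })

  manifest <- list(stages = stages, seed = config$seed,
                   n_genes = cfg$n_genes, n_tissues = cfg$n_tissues,
                   stats = config$stats, thresholds = config$thresholds,
                   package_version = as.character(utils::packageVersion("genediverse")))

  result <- list(annotation = annotation, features = feats,
                 weights = weights_tab, diversity = diversity,
                 complexes = cx, disorder = dis, phenotype = phen,
                 specificity = spec_tab, temporal = temporal,
                 summary = summary, manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(feats, file.path(config$out_dir, "structure.tsv"))
    write_tsv(weights_tab, file.path(config$out_dir, "weights.tsv"))
    write_tsv(diversity, file.path(config$out_dir, "diversity.tsv"))
    write_tsv(cx, file.path(config$out_dir, "complexes.tsv"))
    write_tsv(dis, file.path(config$out_dir, "disorder.tsv"))
    write_tsv(phen, file.path(config$out_dir, "phenotype.tsv"))
    write_tsv(spec_tab, file.path(config$out_dir, "specificity.tsv"))
    write_tsv(summary, file.path(config$out_dir, "summary.tsv"))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(result)
}
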