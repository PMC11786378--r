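# Synthetic-data generators. Every input the pipeline consumes can be
# simulated with known ground truth: annotations with a planted group
# length/exon/isoform shift, an isoform tensor drawn from a hierarchical
# Dirichlet scheme on a specified sample tree, complex tables with
# constitutive and variable members, disorder intervals, a single-rooted
# phenotype DAG with system children, disease annotations with
# somatic/susceptibility flags, and monotone/oscillating temporal
# trajectories. All randomness flows from one integer seed; each generator
# draws from its own offset stream so artifacts are independently
# reproducible.

GROUPS <- c("epigene", "non_epigene", "histone")

#' Simulation configuration
#'
#' Defaults encode the observed world of the human epigene/non-epigene
#' contrast: log10 gene-length parameters back-solved from the reported
#' geometric means and interquartile ranges (41.4 kb IQR 17.4-107.5 for
#' epigenes, 21.8 kb IQR 8.3-62.7 for non-epigenes, 1.5 kb IQR 0.5-2.9 for
#' histones), isoform-count geometric means 8.8 / 6.5 / 1, disorder
#' prevalence 0.83 / 0.55 / 1.0 with maximum-region medians 83 / 51 / 35
#' residues, group fractions from 720 / 19,329 / 100 genes, a 0.68 dominant
#' inheritance rate for epigenes, and complex association rates 0.45 / 0.13
#' with multi-complex rates 0.65 / 0.33.
#'
#' @param seed integer seed; fixed seed implies bit-identical outputs.
#' @param n_genes,n_tissues problem size.
#' @param group_fractions named proportions over epigene / non_epigene /
#'   histone; must sum to 1.
#' @param length_lognormal_params per-group (mu, sigma) of log10 gene span.
#' @param exon_rate per-group mean exons per kb of transcript; 0 gives
#'   single-exon transcripts.
#' @param isoform_count_params per-group (mu, sigma) of log10 isoform count.
#' @param dirichlet_base_concentration symmetric Dirichlet concentration of
#'   the per-gene base isoform profile (< 1 skews toward a dominant
#'   isoform).
#' @param between_tissue_concentration concentration of per-tissue profiles
#'   around the base; large values make tissues share the base profile.
#' @param tree_spec Newick string for the sample tree (leaf count must equal
#'   `n_tissues`); `NULL` for a default two-clade tree.
#' @param complex_params list: constitutive_size, variable_pool_size
#'   (scalar or per group), prob_in_complex, prob_multi (per group).
#' @param disorder_params list: prob_disorder (per group), max_len_log10_mu
#'   (per group), len_log10_sd, protein_len_log10 (mu, sigma), extra_rate.
#' @param ontology_params list: n_systems, terms_per_system.
#' @param disease_params list: prob_disease, prob_somatic,
#'   prob_susceptibility, prob_dominant (per group), max_diseases,
#'   max_terms.
#' @param trajectory_params list: class_mix over increasing / decreasing /
#'   oscillating / flat, noise_sd, n_subregions, ages.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 200L,
                       n_tissues = 8L,
                       group_fractions = c(epigene = 0.036,
                                           non_epigene = 0.959,
                                           histone = 0.005),
                       length_lognormal_params = list(
                         epigene = c(mu = 4.617, sigma = 0.586),
                         non_epigene = c(mu = 4.338, sigma = 0.651),
                         histone = c(mu = 3.176, sigma = 0.569)),
                       exon_rate = c(epigene = 4, non_epigene = 3,
                                     histone = 0.25),
                       isoform_count_params = list(
                         epigene = c(mu = 0.944, sigma = 0.30),
                         non_epigene = c(mu = 0.813, sigma = 0.30),
                         histone = c(mu = 0, sigma = 0.05)),
                       dirichlet_base_concentration = 0.8,
                       between_tissue_concentration = 50,
                       tree_spec = NULL,
                       complex_params = list(
                         constitutive_size = 2L,
                         variable_pool_size = c(epigene = 4L,
                                                non_epigene = 2L,
                                                histone = 1L),
                         prob_in_complex = c(epigene = 0.45,
                                             non_epigene = 0.13,
                                             histone = 0.10),
                         prob_multi = c(epigene = 0.65, non_epigene = 0.33,
                                        histone = 0.20)),
                       disorder_params = list(
                         prob_disorder = c(epigene = 0.83,
                                           non_epigene = 0.55,
                                           histone = 1.0),
                         max_len_log10_mu = c(epigene = log10(83),
                                              non_epigene = log10(51),
                                              histone = log10(35)),
                         len_log10_sd = 0.30,
                         protein_len_log10 = c(mu = 2.75, sigma = 0.25),
                         extra_rate = 0.8),
                       ontology_params = list(n_systems = 11L,
                                              terms_per_system = 4L),
                       disease_params = list(
                         prob_disease = c(epigene = 0.8, non_epigene = 0.5,
                                          histone = 0.2),
                         prob_somatic = 0.10,
                         prob_susceptibility = 0.05,
                         prob_dominant = c(epigene = 0.68,
                                           non_epigene = 0.45,
                                           histone = 0.45),
                         max_diseases = 2L,
                         max_terms = 3L),
                       trajectory_params = list(
                         class_mix = c(increasing = 0.3, decreasing = 0.3,
                                       oscillating = 0.2, flat = 0.2),
                         noise_sd = 0.05,
                         n_subregions = 3L,
                         ages = seq(8, 40, by = 4))) {
  cfg <- list(seed = seed, n_genes = n_genes, n_tissues = n_tissues,
              group_fractions = group_fractions,
              length_lognormal_params = length_lognormal_params,
              exon_rate = exon_rate,
              isoform_count_params = isoform_count_params,
              dirichlet_base_concentration = dirichlet_base_concentration,
              between_tissue_concentration = between_tissue_concentration,
              tree_spec = tree_spec,
              complex_params = complex_params,
              disorder_params = disorder_params,
              ontology_params = ontology_params,
              disease_params = disease_params,
              trajectory_params = trajectory_params)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  fail <- function(field, why) {
    gd_stop(sprintf("invalid config field '%s': %s", field, why),
            "gd_invalid_config")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed) ||
      cfg$seed != round(cfg$seed)) fail("seed", "must be a single integer")
  if (!is.numeric(cfg$n_genes) || cfg$n_genes < 1) {
    fail("n_genes", "must be a positive integer")
  }
  if (!is.numeric(cfg$n_tissues) || cfg$n_tissues < 1) {
    fail("n_tissues", "must be a positive integer")
  }
  gf <- cfg$group_fractions
  if (!setequal(names(gf), GROUPS)) {
    fail("group_fractions", paste("must be named", paste(GROUPS, collapse = "/")))
  }
  if (any(gf < 0) || abs(sum(gf) - 1) > 1e-8) {
    fail("group_fractions", "must be non-negative and sum to 1")
  }
  for (g in GROUPS) {
    p <- cfg$length_lognormal_params[[g]]
    if (is.null(p) || any(!is.finite(p)) || p["sigma"] < 0) {
      fail("length_lognormal_params", sprintf("missing or invalid for %s", g))
    }
    if (is.na(cfg$exon_rate[g]) || cfg$exon_rate[g] < 0) {
      fail("exon_rate", sprintf("missing or negative for %s", g))
    }
    if (is.null(cfg$isoform_count_params[[g]])) {
      fail("isoform_count_params", sprintf("missing for %s", g))
    }
  }
  if (cfg$dirichlet_base_concentration <= 0) {
    fail("dirichlet_base_concentration", "must be > 0")
  }
  if (cfg$between_tissue_concentration <= 0) {
    fail("between_tissue_concentration", "must be > 0")
  }
  cp <- cfg$complex_params
  if (cp$constitutive_size < 0) fail("complex_params", "constitutive_size < 0")
  if (any(per_group(cp$variable_pool_size) < 1)) {
    fail("complex_params", "variable_pool_size must be >= 1")
  }
  tm <- cfg$trajectory_params$class_mix
  if (any(tm < 0) || abs(sum(tm) - 1) > 1e-8) {
    fail("trajectory_params", "class_mix must be non-negative and sum to 1")
  }
  if (cfg$trajectory_params$noise_sd < 0) {
    fail("trajectory_params", "noise_sd must be >= 0")
  }
  structure(cfg, class = "sim_config")
}

# expand a scalar parameter to the named per-group form
per_group <- function(x) {
  if (length(x) == 1 && is.null(names(x))) {
    return(stats::setNames(rep(x, length(GROUPS)), GROUPS))
  }
  x[GROUPS]
}

# artifact-specific seed stream (kept below 2^31)
seed_for <- function(cfg, offset) {
  set.seed((as.integer(cfg$seed) %% 20000000L) * 100L + offset)
}

default_tree_spec <- function(n_tissues) {
  tips <- paste0("T", seq_len(n_tissues))
  if (n_tissues == 1) return(paste0("(", tips, ":1);"))
  half <- ceiling(n_tissues / 2)
  clade <- function(x, bl) {
    if (length(x) == 1) return(paste0(x, ":", bl))
    paste0("(", paste0(x, ":", bl, collapse = ","), "):", bl)
  }
  paste0("(", clade(tips[seq_len(half)], 1), ",",
         clade(tips[(half + 1):n_tissues], 1), ");")
}

sample_groups <- function(cfg, n) {
  gf <- cfg$group_fractions
  sample(names(gf), n, replace = TRUE, prob = gf)
}

#' Generate a synthetic gene/transcript/exon annotation table
#'
#' Gene spans are log10-normal per group; transcript exonic lengths are a
#' Beta-distributed fraction of the span; exon counts are Poisson at the
#' group's exons-per-kb rate (minimum one); exons are placed as a random
#' composition of exonic and intronic stretches inside the span, ranked in
#' transcription order (strand-aware). Exactly one canonical transcript per
#' gene (the longest).
#'
#' @param config a [sim_config].
#' @return an [annotation_table]; gene groups are in `$genes$group`.
#' @export
gen_annotation <- function(config) {
  config <- validate_sim_config(config)
  seed_for(config, 1L)
  n <- config$n_genes
  groups <- sample_groups(config, n)
  mu <- vapply(config$length_lognormal_params, `[[`, numeric(1), "mu")
  sigma <- vapply(config$length_lognormal_params, `[[`, numeric(1), "sigma")
  span <- pmax(300L, as.integer(round(10^stats::rnorm(n, mu[groups],
                                                      sigma[groups]))))
  chrom <- sample(paste0("chr", 1:22), n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  # lay genes end to end per chromosome with fixed gaps
  start <- integer(n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    start[idx] <- cumsum(c(1L, utils::head(span[idx], -1) + 10000L))
  }
  genes <- data.frame(gene_id = sprintf("G%05d", seq_len(n)), group = groups,
                      chromosome = chrom, start = start,
                      end = start + span - 1L, strand = strand,
                      biotype = "protein_coding", stringsAsFactors = FALSE)

  iso_mu <- vapply(config$isoform_count_params, `[[`, numeric(1), "mu")
  iso_sd <- vapply(config$isoform_count_params, `[[`, numeric(1), "sigma")
  rate <- per_group(config$exon_rate)

  tx_list <- vector("list", n)
  ex_list <- vector("list", n)
  for (i in seq_len(n)) {
    g <- groups[i]
    n_tx <- max(1L, as.integer(round(10^stats::rnorm(1, iso_mu[g], iso_sd[g]))))
    tx_ids <- sprintf("%s.t%02d", genes$gene_id[i], seq_len(n_tx))
    ex_rows <- vector("list", n_tx)
    ex_total <- integer(n_tx)
    for (j in seq_len(n_tx)) {
      # exonic length: Beta(2, 8) fraction of the span, bounded to leave
      # room for introns between up to k exons
      frac <- stats::rbeta(1, 2, 8)
      ex_len <- max(60L, as.integer(round(span[i] * frac)))
      k <- if (rate[g] == 0) 1L else
        max(1L, stats::rpois(1, rate[g] * ex_len / 1000))
      k <- min(k, ex_len %/% 20L, (span[i] - ex_len) %/% 20L + 1L)
      k <- max(k, 1L)
      ex_len <- min(ex_len, span[i] - (k - 1L)) # introns need >= 1 nt each
      exon_lens <- rcomposition(ex_len, k, minimum = 1L)
      gaps <- if (k == 1) {
        rcomposition(span[i] - ex_len, 2L, minimum = 0L)
      } else {
        inner <- rcomposition(span[i] - ex_len - (k - 1L), k + 1L, minimum = 0L)
        inner[2:k] <- inner[2:k] + 1L
        inner
      }
      starts <- genes$start[i] +
        cumsum(c(0L, exon_lens[-k] + gaps[2:k][seq_len(k - 1)])) + gaps[1]
      ends <- starts + exon_lens - 1L
      rank <- if (strand[i] == "+") seq_len(k) else rev(seq_len(k))
      ex_rows[[j]] <- data.frame(transcript_id = tx_ids[j], start = starts,
                                 end = ends, rank = rank,
                                 stringsAsFactors = FALSE)
      ex_total[j] <- sum(exon_lens)
    }
    canonical <- seq_len(n_tx) == which.max(ex_total)
    tx_list[[i]] <- data.frame(transcript_id = tx_ids,
                               gene_id = genes$gene_id[i],
                               canonical = canonical, stringsAsFactors = FALSE)
    ex_list[[i]] <- do.call(rbind, ex_rows)
  }
  annotation_table(genes, do.call(rbind, tx_list), do.call(rbind, ex_list))
}

# Brownian-motion trait along the tree: child = parent + N(0, sig2 * branch).
# Gives per-gene expression scales whose between-tissue correlation mirrors
# the tree, so sample clustering can recover the generating topology.
bm_trait <- function(tree, sig2) {
  x <- numeric(max(tree$edge))
  cw <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(cw$edge))) {
    x[cw$edge[i, 2]] <- x[cw$edge[i, 1]] +
      stats::rnorm(1, 0, sqrt(sig2 * cw$edge.length[i]))
  }
  x[seq_along(tree$tip.label)]
}

#' Generate an isoform expression tensor on a known sample tree
#'
#' Per gene, a base isoform-proportion vector is drawn from a symmetric
#' Dirichlet(`dirichlet_base_concentration`); each tissue's proportions are
#' drawn from Dirichlet(`between_tissue_concentration` x base), so large
#' concentrations make tissue profiles converge to the base. Per-gene total
#' expression scales follow a log-normal whose log10 mean drifts along the
#' tree as Brownian motion (variance 0.25 per unit branch length, plus
#' 0.1 sd of tissue-independent noise), so closely related samples have
#' correlated expression. The sample tree is the tree_spec (or a default
#' two-clade tree) and is returned as ground truth.
#'
#' @param config a [sim_config].
#' @param annotation optional [annotation_table] whose transcripts define
#'   the isoform sets (ids are reused); drawn fresh from
#'   `isoform_count_params` when omitted.
#' @return list with `tensor` ([isoform_tensor]), `tree` ([ape::phylo]) and
#'   `truth` (per-gene base profiles).
#' @export
gen_isoform_tensor <- function(config, annotation = NULL) {
  config <- validate_sim_config(config)
  spec <- config$tree_spec %||% default_tree_spec(config$n_tissues)
  tree <- ape::read.tree(text = spec)
  if (length(tree$tip.label) != config$n_tissues) {
    gd_stop(sprintf("tree_spec has %d leaves but n_tissues = %d",
                    length(tree$tip.label), config$n_tissues),
            "gd_invalid_config")
  }
  seed_for(config, 2L)
  if (is.null(annotation)) {
    groups <- sample_groups(config, config$n_genes)
    iso_mu <- vapply(config$isoform_count_params, `[[`, numeric(1), "mu")
    iso_sd <- vapply(config$isoform_count_params, `[[`, numeric(1), "sigma")
    n_iso <- pmax(1L, as.integer(round(10^stats::rnorm(
      config$n_genes, iso_mu[groups], iso_sd[groups]))))
    gene_ids <- sprintf("G%05d", seq_len(config$n_genes))
    map <- data.frame(
      transcript_id = unlist(mapply(function(g, k) sprintf("%s.t%02d", g, 1:k),
                                    gene_ids, n_iso, SIMPLIFY = FALSE)),
      gene_id = rep(gene_ids, n_iso), stringsAsFactors = FALSE)
    gene_groups <- stats::setNames(groups, gene_ids)
  } else {
    map <- annotation$transcripts[, c("transcript_id", "gene_id")]
    gene_groups <- stats::setNames(annotation$genes$group,
                                   annotation$genes$gene_id)
  }
  samples <- tree$tip.label
  abund <- matrix(0, nrow(map), length(samples),
                  dimnames = list(map$transcript_id, samples))
  base_profiles <- list()
  a0 <- config$dirichlet_base_concentration
  c_bt <- config$between_tissue_concentration
  for (g in unique(map$gene_id)) {
    tx <- map$transcript_id[map$gene_id == g]
    k <- length(tx)
    base <- if (k == 1) 1 else rdirichlet1(rep(a0, k))
    base_profiles[[g]] <- stats::setNames(base, tx)
    scales <- 10^(stats::rnorm(1, 1.2, 0.4) + bm_trait(tree, 0.25) +
                    stats::rnorm(length(samples), 0, 0.1))
    props <- if (k == 1) matrix(1, 1, length(samples)) else
      vapply(seq_along(samples),
             function(t) rdirichlet1(c_bt * base), numeric(k))
    abund[tx, ] <- sweep(matrix(props, k, length(samples)), 2, scales, "*")
  }
  list(tensor = isoform_tensor(abund, map), tree = tree,
       truth = list(base_profiles = base_profiles, groups = gene_groups))
}

#' Generate a complex table with known partner structure
#'
#' Each focal gene is associated with a complex with its group's
#' `prob_in_complex`; associated genes are multi-complex with `prob_multi`,
#' in which case they receive `variable_pool_size` complexes, each holding
#' the focal gene, a shared constitutive set of size `constitutive_size`,
#' and one distinct variable member — so the true variable-partner count
#' equals the pool size. Ground truth is attached as attribute `truth`.
#'
#' @param config a [sim_config].
#' @param genes,groups focal gene ids and their group labels; simulated from
#'   `group_fractions` when omitted.
#' @return a [complex_table] with a `truth` attribute (data.frame gene_id,
#'   group, n_complexes, n_variable).
#' @export
gen_complex_table <- function(config, genes = NULL, groups = NULL) {
  config <- validate_sim_config(config)
  seed_for(config, 3L)
  if (is.null(genes)) {
    genes <- sprintf("G%05d", seq_len(config$n_genes))
    groups <- sample_groups(config, config$n_genes)
  }
  check_that(length(genes) == length(groups), "genes and groups must match")
  cp <- config$complex_params
  pool_size <- per_group(cp$variable_pool_size)
  p_in <- per_group(cp$prob_in_complex)
  p_multi <- per_group(cp$prob_multi)
  members <- list()
  truth <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]; gr <- groups[i]
    in_complex <- stats::runif(1) < p_in[gr]
    if (!in_complex) {
      truth[[i]] <- data.frame(gene_id = g, group = gr, n_complexes = 0L,
                               n_variable = NA_integer_,
                               stringsAsFactors = FALSE)
      next
    }
    const <- if (cp$constitutive_size > 0)
      sprintf("%s_const%d", g, seq_len(cp$constitutive_size)) else character(0)
    multi <- stats::runif(1) < p_multi[gr]
    k <- if (multi) pool_size[gr] else 1L
    vars <- sprintf("%s_var%d", g, seq_len(k))
    for (j in seq_len(k)) {
      members[[sprintf("CPX-%s-%d", g, j)]] <- c(g, const, vars[j])
    }
    truth[[i]] <- data.frame(gene_id = g, group = gr, n_complexes = k,
                             n_variable = if (k >= 2) k else NA_integer_,
                             stringsAsFactors = FALSE)
  }
  check_that(length(members) > 0, "no complexes generated; raise prob_in_complex")
  tab <- complex_table(members)
  attr(tab, "truth") <- do.call(rbind, truth)
  tab
}

#' Generate a protein disorder interval table
#'
#' Protein lengths are log10-normal; each protein carries at least one
#' disordered region with its group's `prob_disorder`; region lengths are
#' log10-normal around the group's maximum-region median, clipped to the
#' protein, and placed uniformly (they may overlap).
#'
#' @param config a [sim_config].
#' @param genes,groups protein ids and group labels; simulated when omitted.
#' @return data.frame (protein_id, group, length, start, end — one row per
#'   interval, NA start/end for proteins without disorder) with a `truth`
#'   attribute recording per-protein has_disorder.
#' @export
gen_disorder_table <- function(config, genes = NULL, groups = NULL) {
  config <- validate_sim_config(config)
  seed_for(config, 4L)
  if (is.null(genes)) {
    genes <- sprintf("G%05d", seq_len(config$n_genes))
    groups <- sample_groups(config, config$n_genes)
  }
  dp <- config$disorder_params
  p_dis <- per_group(dp$prob_disorder)
  mu_len <- per_group(dp$max_len_log10_mu)
  plen <- pmax(50L, as.integer(round(10^stats::rnorm(
    length(genes), dp$protein_len_log10["mu"], dp$protein_len_log10["sigma"]))))
  rows <- vector("list", length(genes))
  truth <- logical(length(genes))
  for (i in seq_along(genes)) {
    gr <- groups[i]
    truth[i] <- stats::runif(1) < p_dis[gr]
    if (!truth[i]) {
      rows[[i]] <- data.frame(protein_id = genes[i], group = gr,
                              length = plen[i], start = NA_integer_,
                              end = NA_integer_, stringsAsFactors = FALSE)
      next
    }
    n_int <- 1L + stats::rpois(1, dp$extra_rate)
    lens <- pmin(plen[i],
                 pmax(1L, as.integer(round(10^stats::rnorm(
                   n_int, mu_len[gr], dp$len_log10_sd)))))
    starts <- vapply(lens, function(L)
      sample.int(plen[i] - L + 1L, 1L), integer(1))
    rows[[i]] <- data.frame(protein_id = genes[i], group = gr,
                            length = plen[i], start = starts,
                            end = starts + lens - 1L, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- data.frame(protein_id = genes, group = groups,
                                   has_disorder = truth,
                                   stringsAsFactors = FALSE)
  out
}

#' Generate a single-rooted phenotype DAG
#'
#' A root phenotypic-abnormality term with `n_systems` direct children (the
#' major body systems); each system has `terms_per_system` leaf terms plus
#' one mid-level term with its own leaf. One extra leaf is attached under
#' the first two systems to exercise multi-parent (DAG) traversal.
#'
#' @param config a [sim_config].
#' @return list with `graph` ([ontology_graph]), `root`, `systems`, and
#'   `term_system` (named list mapping each non-root term to its system
#'   set — the ground truth for closure tests).
#' @export
gen_ontology <- function(config) {
  config <- validate_sim_config(config)
  op <- config$ontology_params
  check_that(op$n_systems >= 2, "ontology needs >= 2 systems")
  root <- "PHEN:ROOT"
  systems <- sprintf("SYS:%02d", seq_len(op$n_systems))
  edges <- data.frame(child = systems, parent = root,
                      stringsAsFactors = FALSE)
  term_system <- stats::setNames(as.list(systems), systems)
  for (s in systems) {
    leaves <- sprintf("%s.L%d", s, seq_len(op$terms_per_system))
    mid <- sprintf("%s.M1", s)
    midleaf <- sprintf("%s.M1.L1", s)
    edges <- rbind(edges,
                   data.frame(child = c(leaves, mid, midleaf),
                              parent = c(rep(s, length(leaves)), s, mid),
                              stringsAsFactors = FALSE))
    for (t in c(leaves, mid, midleaf)) term_system[[t]] <- s
  }
  multi <- "XP:MULTI.L1"
  edges <- rbind(edges, data.frame(child = multi,
                                   parent = c(systems[1], systems[2]),
                                   stringsAsFactors = FALSE))
  term_system[[multi]] <- systems[1:2]
  list(graph = ontology_graph(edges, root = root), root = root,
       systems = systems, term_system = term_system)
}

#' Generate gene-disease-term annotations
#'
#' Each gene acquires diseases with its group's `prob_disease`; each disease
#' carries 1..max_terms ontology terms, an inheritance mode (dominant with
#' the group's `prob_dominant`, else recessive or other), and independent
#' somatic / susceptibility flags. Ground truth records which rows survive
#' filtering and each gene's true post-filter system set.
#'
#' @param config a [sim_config].
#' @param ontology result of [gen_ontology].
#' @param genes,groups gene ids and labels; simulated when omitted.
#' @return annotations data.frame with a `truth` attribute (list: retained
#'   logical per row, systems_per_gene named list).
#' @export
gen_disease_annotations <- function(config, ontology, genes = NULL,
                                    groups = NULL) {
  config <- validate_sim_config(config)
  seed_for(config, 5L)
  if (is.null(genes)) {
    genes <- sprintf("G%05d", seq_len(config$n_genes))
    groups <- sample_groups(config, config$n_genes)
  }
  dp <- config$disease_params
  p_dis <- per_group(dp$prob_disease)
  p_dom <- per_group(dp$prob_dominant)
  terms_pool <- setdiff(names(ontology$term_system), ontology$systems)
  rows <- list()
  d_id <- 0L
  for (i in seq_along(genes)) {
    gr <- groups[i]
    if (stats::runif(1) >= p_dis[gr]) next
    for (d in seq_len(sample.int(dp$max_diseases, 1))) {
      d_id <- d_id + 1L
      terms <- sample(terms_pool, sample.int(dp$max_terms, 1))
      mode <- if (stats::runif(1) < p_dom[gr]) "Autosomal dominant" else
        sample(c("Autosomal recessive", "Multifactorial"), 1)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = genes[i], disease_id = sprintf("DIS:%05d", d_id),
        modes = mode,
        somatic = stats::runif(1) < dp$prob_somatic,
        susceptibility = stats::runif(1) < dp$prob_susceptibility,
        terms = paste(terms, collapse = ";"), stringsAsFactors = FALSE)
    }
  }
  ann <- do.call(rbind, rows)
  retained <- !ann$somatic & !ann$susceptibility
  kept <- ann[retained, , drop = FALSE]
  truth_systems <- lapply(split(kept$terms, kept$gene_id), function(tt) {
    sort(unique(unlist(ontology$term_system[unlist(split_field(tt))])))
  })
  attr(ann, "truth") <- list(retained = retained,
                             systems_per_gene = truth_systems)
  ann
}

trajectory_shape <- function(class, s) {
  switch(class,
         increasing = 0.1 + 0.9 * stats::plogis((s - 0.5) * 8),
         decreasing = 0.1 + 0.9 * stats::plogis((0.5 - s) * 8),
         oscillating = 0.55 + 0.45 * sin(2 * pi * 2 * s),
         flat = rep(0.6, length(s)),
         gd_stop(paste("unknown trajectory class:", class),
                 "gd_invalid_config"))
}

#' Generate temporal expression trajectories with planted classes
#'
#' Each gene carries a ground-truth trajectory class (increasing /
#' decreasing / oscillating / flat per `class_mix`); its expression at age a
#' is `base * (shape(a / max_age) + N(0, noise_sd))`, clipped at zero, with
#' a log-normal per-gene base level. The same classes are planted in every
#' subregion (shared class labels, independent noise).
#'
#' @param config a [sim_config].
#' @return list with `samples` (long data.frame: subregion, age_pcw, gene,
#'   value, units) and `truth` (named class per gene).
#' @export
gen_temporal_profiles <- function(config) {
  config <- validate_sim_config(config)
  seed_for(config, 6L)
  tp <- config$trajectory_params
  n <- config$n_genes
  classes <- sample(names(tp$class_mix), n, replace = TRUE,
                    prob = tp$class_mix)
  genes <- sprintf("G%05d", seq_len(n))
  base <- 10^stats::rnorm(n, 1.5, 0.4)
  ages <- tp$ages
  check_that(all(diff(ages) > 0), "trajectory ages must be strictly increasing")
  s <- ages / max(ages)
  rows <- list()
  for (r in seq_len(tp$n_subregions)) {
    sub <- sprintf("R%02d", r)
    for (i in seq_len(n)) {
      shape <- trajectory_shape(classes[i], s)
      val <- base[i] * pmax(0, shape + stats::rnorm(length(s), 0, tp$noise_sd))
      rows[[length(rows) + 1L]] <- data.frame(
        subregion = sub, age_pcw = ages, gene = genes[i], value = val,
        units = "RPKM", stringsAsFactors = FALSE)
    }
  }
  list(samples = do.call(rbind, rows),
       truth = stats::setNames(classes, genes))
}
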