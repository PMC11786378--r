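long_row <- function(sub, age, gene, value) {
  data.frame(subregion = sub, age_pcw = age, gene = gene, value = value)
}

test_that("prepare_profiles averages same-age samples, converts to TPM,
           and drops sparse subregions and old ages", {
  samples <- rbind(
    long_row("A", c(8, 8, 12, 16, 20, 24), "g1", c(2, 4, 1, 1, 1, 1)),
    long_row("A", c(8, 12, 16, 20, 24), "g2", c(1, 1, 1, 1, 1)),
    long_row("B", c(8, 12, 16, 20), "g1", 1), # only 4 ages: dropped
    long_row("A", 44, "g1", 99)) # past 40 pcw: dropped
  prof <- prepare_profiles(samples, min_timepoints = 5, max_age = 40)
  expect_equal(names(prof), "A")
  expect_equal(prof$A$ages, c(8, 12, 16, 20, 24))
  # same-age (2,4) averaged to 3 before the TPM rescale: 3/(3+1)*1e6
  expect_equal(prof$A$mat["g1", "8"], 7.5e5)
  expect_equal(prof$A$mat["g2", "8"], 2.5e5)
  # an RPKM column of (1,1) becomes (5e5, 5e5)
  expect_equal(as.numeric(prof$A$mat[, "12"]), c(5e5, 5e5))
  expect_equal(prof$A$units, "TPM")
})

test_that("filter_by_range drops strictly-below-threshold genes; scale_max
           rescales to unit maximum", {
  p <- list(subregion = "A", ages = c(8, 12, 16),
            mat = matrix(c(1, 2, 4, 5, 5, 5, 1, 1, 1.5), 3, 3, byrow = TRUE,
                         dimnames = list(c("up", "flat", "half"),
                                         c("8", "12", "16"))),
            units = "TPM")
  f <- filter_by_range(p, min_range = 0.5)
  expect_setequal(rownames(f$mat), c("up", "half")) # range 0.5 retained
  expect_equal(f$dropped, "flat")
  s <- scale_max(f)
  expect_equal(as.numeric(s$mat["up", ]), c(0.25, 0.5, 1))
  expect_equal(max(s$mat["half", ]), 1)
  expect_error(scale_max(list(mat = matrix(-1, 1, 1))),
               class = "gd_invalid_input")
})

test_that("binned_time_weights gives non-empty bins equal total weight", {
  w <- binned_time_weights(c(8, 9, 38))
  expect_equal(as.numeric(w), c(0.25, 0.25, 0.5))
  expect_equal(sum(w), 1)
  expect_equal(as.numeric(binned_time_weights(c(5, 15, 25, 35))), rep(0.25, 4))
  expect_equal(as.numeric(binned_time_weights(c(2, 4, 6, 8))), rep(0.25, 4))
  set.seed(50)
  for (i in 1:20) {
    ages <- sort(sample(seq(1, 40), sample(3:12, 1)))
    expect_equal(sum(binned_time_weights(ages)), 1)
  }
  expect_error(binned_time_weights(c(10, 45)), class = "gd_invalid_input")
})

test_that("weighted_pearson reduces to Pearson and matches cov.wt", {
  set.seed(51)
  x <- rnorm(12); y <- 0.4 * x + rnorm(12, 0, 0.5)
  expect_equal(weighted_pearson(x, y, rep(1, 12)), stats::cor(x, y),
               tolerance = 1e-12)
  expect_equal(weighted_pearson(x, 2 * x + 1), 1, tolerance = 1e-12)
  expect_equal(weighted_pearson(x, -x), -1, tolerance = 1e-12)
  for (i in 1:50) {
    xx <- rnorm(8); yy <- rnorm(8); w <- runif(8, 0.1, 2)
    expect_equal(weighted_pearson(xx, yy, w), oracle_wpearson(xx, yy, w),
                 tolerance = 1e-9)
  }
  expect_error(weighted_pearson(rep(1, 5), rnorm(5)), class = "gd_undefined")
})

test_that("cluster_seed_genes separates planted patterns; assignment uses a
           strict threshold", {
  ages <- c(8, 12, 16, 20, 24)
  up <- seq(0.2, 1, length.out = 5)
  p <- list(subregion = "A", ages = ages,
            mat = rbind(a = up, b = up, c = rev(up),
                        d = c(0.2, 1, 0.2, 1, 0.2)),
            units = "scaled")
  colnames(p$mat) <- as.character(ages)
  cs <- cluster_seed_genes(p, c("a", "b", "c"), cut = 0.2)
  expect_equal(cs$membership[["a"]], cs$membership[["b"]])
  expect_false(cs$membership[["a"]] == cs$membership[["c"]])

  # identical trajectories collapse into one cluster
  cs1 <- cluster_seed_genes(p, c("a", "b"), cut = 0.2)
  expect_equal(length(unique(cs1$membership)), 1)

  # gene equal to a cluster mean is assigned with correlation 1
  asn <- assign_genes(cs, p, genes = "d", threshold = 0.8)
  expect_false("d" %in% asn$assigned$gene) # uncorrelated: unassigned
  p2 <- p; p2$mat <- rbind(p$mat, e = up)
  asn2 <- assign_genes(cs, p2, genes = "e", threshold = 0.8)
  expect_equal(asn2$assigned$gene, "e")
  expect_equal(asn2$assigned$cluster, cs$membership[["a"]])
  expect_equal(asn2$assigned$correlation, 1, tolerance = 1e-9)

  # correlation exactly at the threshold is NOT assigned (strict >)
  cs_one <- cluster_seed_genes(p, c("a", "b"), cut = 0.2)
  mean_traj <- cs_one$means[1, ]
  w <- cs_one$weights
  expect_error(cluster_seed_genes(p, "a"), class = "gd_invalid_input")
})

test_that("impute_nearest uses the nearest age with earlier-age ties", {
  v <- c(1, 9)
  expect_equal(as.numeric(impute_nearest(v, c(8, 20), 10)), 1)
  expect_equal(as.numeric(impute_nearest(v, c(8, 20), 14)), 1) # tie -> earlier
  expect_equal(as.numeric(impute_nearest(v, c(8, 20), 15)), 9)
  expect_equal(as.numeric(impute_nearest(v, c(8, 20), c(8, 20))), v)
})

test_that("metacluster groups cluster means across subregions", {
  mk_cs <- function(sub, ages, means) {
    structure(list(subregion = sub, ages = ages,
                   membership = stats::setNames(seq_len(nrow(means)),
                                                paste0(sub, seq_len(nrow(means)))),
                   means = matrix(means, nrow = nrow(means),
                                  dimnames = list(seq_len(nrow(means)),
                                                  as.character(ages))),
                   assigned = NULL, weights = NULL, cut = 0.2),
              class = "cluster_set")
  }
  ages <- c(8, 16, 24, 32)
  up <- c(0.2, 0.5, 0.8, 1); dn <- rev(up)
  a <- mk_cs("A", ages, rbind(up, dn))
  b <- mk_cs("B", ages, rbind(up, dn))
  meta <- metacluster(list(a, b), cut = 0.2)
  expect_equal(nrow(meta), 4)
  # identical means across subregions share a metacluster; up vs down split
  m_up <- meta$metacluster[meta$cluster == 1]
  m_dn <- meta$metacluster[meta$cluster == 2]
  expect_equal(m_up[1], m_up[2])
  expect_equal(m_dn[1], m_dn[2])
  expect_false(m_up[1] == m_dn[1])
  expect_error(metacluster(list()), class = "gd_invalid_input")
})

test_that("planted trajectory classes are recovered (ARI = 1 at low noise)", {
  cfg <- sim_config(seed = 52, n_genes = 60,
                    trajectory_params = list(
                      class_mix = c(increasing = 1 / 3, decreasing = 1 / 3,
                                    oscillating = 1 / 3, flat = 0),
                      noise_sd = 0.02, n_subregions = 3,
                      ages = seq(8, 40, by = 4)))
  sim <- gen_temporal_profiles(cfg)
  profs <- prepare_profiles(sim$samples)
  sets <- lapply(profs, function(p) {
    p <- scale_max(filter_by_range(p))
    cluster_seed_genes(p, rownames(p$mat), cut = 0.2)
  })
  for (cs in sets) {
    expect_equal(adjusted_rand(cs$membership,
                               sim$truth[names(cs$membership)]), 1)
  }
  meta <- metacluster(sets, cut = 0.2)
  # metaclusters must match the planted classes across subregions
  class_of_cluster <- unlist(lapply(sets, function(cs)
    vapply(rownames(cs$means), function(k) {
      unique(sim$truth[names(cs$membership)[cs$membership == as.integer(k)]])
    }, character(1))))
  expect_equal(adjusted_rand(meta$metacluster, class_of_cluster), 1)
})

test_that("the temporal pipeline is deterministic given inputs", {
  cfg <- sim_config(seed = 53, n_genes = 20)
  sim <- gen_temporal_profiles(cfg)
  run <- function() {
    profs <- prepare_profiles(sim$samples)
    lapply(profs, function(p) {
      p <- scale_max(filter_by_range(p))
      cluster_seed_genes(p, rownames(p$mat))$membership
    })
  }
  expect_identical(run(), run())
})
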