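two_sample_tensor <- function(p1, p2) {
  make_tensor(list(g = cbind(p1, p2) * 10), c("s1", "s2"))
}

test_that("isoform_proportions normalizes within sample", {
  tn <- make_tensor(list(g = cbind(c(3, 1), c(5, 0), c(0, 0))),
                    c("s1", "s2", "s3"))
  expect_equal(as.numeric(isoform_proportions(tn, "g", "s1")), c(0.75, 0.25))
  expect_equal(as.numeric(isoform_proportions(tn, "g", "s2")), c(1, 0))
  expect_error(isoform_proportions(tn, "g", "s3"), class = "gd_unexpressed")
})

test_that("tissue_entropy reproduces the printed worked examples", {
  expect_equal(tissue_entropy(rep(0.25, 4)), 2)
  expect_equal(tissue_entropy(1), 0)
  expect_equal(tissue_entropy(c(0.5, 0.25, 0.25)), 1.5)
  expect_equal(tissue_entropy(c(1, 0, 0)), 0)
  expect_error(tissue_entropy(c(1.2, -0.2)), class = "gd_invalid_input")
})

test_that("tissue_entropy and effective count match the brute-force oracle", {
  set.seed(10)
  for (i in 1:100) {
    p <- rdirichlet1(runif(sample(2:8, 1), 0.3, 3))
    expect_equal(tissue_entropy(p), oracle_entropy(p), tolerance = 1e-12)
    expect_lte(tissue_entropy(p), log2(length(p)) + 1e-12)
  }
  expect_equal(round(effective_isoform_count(2.1), 1), 4.3)
  # the published "3.3" reflects the unrounded mean entropy (2^1.7 = 3.25)
  expect_equal(effective_isoform_count(1.7), 3.3, tolerance = 0.02)
  expect_equal(effective_isoform_count(0), 1)
})

test_that("mean_intratissue_entropy is a weighted mean over expressed samples", {
  # H = (2, 0) across the two samples
  tn <- make_tensor(list(g = cbind(rep(2.5, 4), c(10, 0, 0, 0))),
                    c("s1", "s2"))
  expect_equal(mean_intratissue_entropy(tn, "g",
                                        c(s1 = 1, s2 = 1)), 1)
  expect_equal(mean_intratissue_entropy(tn, "g",
                                        c(s1 = 1, s2 = 0)), 2)
  # identical proportions everywhere: mean equals per-sample entropy
  tn2 <- make_tensor(list(g = cbind(c(6, 2), c(3, 1))), c("s1", "s2"))
  expect_equal(mean_intratissue_entropy(tn2, "g", c(s1 = 0.3, s2 = 0.9)),
               tissue_entropy(c(0.75, 0.25)))
  # single-isoform genes are excluded
  tn3 <- make_tensor(list(g = matrix(c(1, 2), 1)), c("s1", "s2"))
  expect_error(mean_intratissue_entropy(tn3, "g"),
               class = "gd_excluded_input")
})

test_that("mean_profile is the weighted mean proportion vector", {
  tn <- two_sample_tensor(c(1, 0), c(0, 1))
  expect_equal(as.numeric(mean_profile(tn, "g", c(s1 = 1, s2 = 1))),
               c(0.5, 0.5))
  expect_equal(as.numeric(mean_profile(tn, "g", c(s1 = 1, s2 = 0))),
               c(1, 0))
  expect_equal(sum(mean_profile(tn, "g", c(s1 = 0.4, s2 = 0.7))), 1,
               tolerance = 1e-9)
})

test_that("mean_intertissue_divergence matches hand values and the oracle", {
  shared <- two_sample_tensor(c(0.6, 0.4), c(0.6, 0.4))
  expect_equal(mean_intertissue_divergence(shared, "g", c(s1 = 1, s2 = 1)), 0)

  opposite <- two_sample_tensor(c(1, 0), c(0, 1))
  expect_equal(mean_intertissue_divergence(opposite, "g",
                                           c(s1 = 1, s2 = 1)), 1)

  # a zero-weight divergent sample changes nothing
  tn3 <- make_tensor(list(g = cbind(c(6, 4), c(6, 4), c(0, 10))),
                     c("s1", "s2", "s3"))
  expect_equal(mean_intertissue_divergence(tn3, "g",
                                           c(s1 = 1, s2 = 1, s3 = 0)), 0)

  set.seed(11)
  for (i in 1:60) {
    k <- sample(2:5, 1); m <- sample(2:6, 1)
    abund <- matrix(rexp(k * m), k, m) *
      matrix(rbinom(k * m, 1, 0.8), k, m)
    abund[1, colSums(abund) == 0] <- 1
    samples <- paste0("s", 1:m)
    dimnames(abund) <- list(paste0("g.t", 1:k), samples)
    w <- stats::setNames(runif(m), samples)
    tn <- isoform_tensor(abund, data.frame(transcript_id = rownames(abund),
                                           gene_id = "g"))
    expect_equal(mean_intertissue_divergence(tn, "g", w),
                 oracle_mean_divergence(abund, w), tolerance = 1e-9)
  }
})

test_that("entropy and divergence are invariant to isoform relabeling", {
  set.seed(12)
  abund <- matrix(rexp(12), 3, 4,
                  dimnames = list(paste0("g.t", 1:3), paste0("s", 1:4)))
  w <- stats::setNames(runif(4, 0.2, 1), paste0("s", 1:4))
  tn <- isoform_tensor(abund, data.frame(transcript_id = rownames(abund),
                                         gene_id = "g"))
  perm <- abund[c(3, 1, 2), ]
  rownames(perm) <- paste0("g.t", 1:3)
  tnp <- isoform_tensor(perm, data.frame(transcript_id = rownames(perm),
                                         gene_id = "g"))
  expect_equal(mean_intratissue_entropy(tn, "g", w),
               mean_intratissue_entropy(tnp, "g", w), tolerance = 1e-12)
  expect_equal(mean_intertissue_divergence(tn, "g", w),
               mean_intertissue_divergence(tnp, "g", w), tolerance = 1e-12)
})

test_that("diversity_table flags excluded genes and bounds entropy", {
  cfg <- sim_config(seed = 13, n_genes = 25, n_tissues = 5,
                    group_fractions = c(epigene = 0.3, non_epigene = 0.5,
                                        histone = 0.2))
  sim <- gen_isoform_tensor(cfg)
  d <- diversity_table(sim$tensor, sim$tree)
  expect_setequal(d$gene_id, names(sim$tensor$genes))
  single <- d$n_isoforms == 1
  expect_true(all(d$excluded[single]))
  ok <- !d$excluded
  expect_true(all(d$mean_entropy_bits[ok] <= log2(d$n_isoforms[ok]) + 1e-9))
  expect_true(all(d$mean_divergence_bits[ok] >= 0))
  expect_equal(d$effective_isoforms[ok], 2^d$mean_entropy_bits[ok])
})
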