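test_that("gene_length is the strand-independent genomic span", {
  expect_equal(gene_length(101, 200), 100L)
  expect_equal(gene_length(5, 5), 1L)
  expect_error(gene_length(10, 5), class = "gd_invalid_input")
})

test_that("transcript_length sums exon lengths and rejects overlaps", {
  expect_equal(transcript_length(data.frame(start = c(1, 201),
                                            end = c(100, 300))), 200L)
  expect_equal(transcript_length(data.frame(start = 1, end = 603)), 603L)
  expect_error(
    transcript_length(data.frame(start = c(1, 50), end = c(100, 120))),
    class = "gd_invalid_input")
  expect_error(transcript_length(data.frame(start = integer(0),
                                            end = integer(0))),
               class = "gd_invalid_input")
})

test_that("exon_partition splits by transcription-order rank", {
  ex <- data.frame(start = c(1, 201, 501), end = c(100, 400, 600), rank = 1:3)
  p <- exon_partition(ex)
  expect_equal(c(p$first_prop, p$middle_prop, p$last_prop),
               c(0.25, 0.5, 0.25))

  # minus strand: ranks reversed relative to coordinates, same lengths
  exm <- data.frame(start = c(1, 201, 501), end = c(100, 400, 600),
                    rank = 3:1)
  pm <- exon_partition(exm)
  expect_equal(c(pm$first_prop, pm$middle_prop, pm$last_prop),
               c(0.25, 0.5, 0.25))

  # two exons: middle absent (NA), not zero
  p2 <- exon_partition(data.frame(start = c(1, 200), end = c(150, 249),
                                  rank = 1:2))
  expect_equal(p2$first_prop, 0.75)
  expect_equal(p2$last_prop, 0.25)
  expect_true(is.na(p2$middle_prop))

  expect_error(exon_partition(data.frame(start = 1, end = 10, rank = 1)),
               class = "gd_excluded_input")
})

test_that("exon partition proportions sum to 1 on generated annotations", {
  cfg <- sim_config(seed = 11, n_genes = 40,
                    group_fractions = c(epigene = 0.4, non_epigene = 0.5,
                                        histone = 0.1))
  ann <- gen_annotation(cfg)
  feats <- structure_features(ann)
  multi <- feats[feats$exon_count >= 3, ]
  expect_gt(nrow(multi), 0)
  expect_equal(multi$first_prop + multi$middle_prop + multi$last_prop,
               rep(1, nrow(multi)), tolerance = 1e-9)
  expect_true(all(feats$transcript_length <= feats$gene_length))
})

test_that("single_exon_fraction counts canonical transcripts", {
  genes <- data.frame(gene_id = paste0("g", 1:4), group = "x",
                      chromosome = "chr1", start = c(1, 101, 201, 301) * 100,
                      end = c(99, 199, 299, 399) * 100, strand = "+")
  tx <- data.frame(transcript_id = paste0("t", 1:4),
                   gene_id = paste0("g", 1:4), canonical = TRUE)
  ex <- rbind(
    data.frame(transcript_id = "t1", start = 100, end = 200, rank = 1),
    data.frame(transcript_id = c("t2", "t2"), start = c(10100, 10400),
               end = c(10200, 10500), rank = 1:2),
    data.frame(transcript_id = c("t3", "t3"), start = c(20100, 20400),
               end = c(20200, 20500), rank = 1:2),
    data.frame(transcript_id = c("t4", "t4"), start = c(30100, 30400),
               end = c(30200, 30500), rank = 1:2))
  ann <- annotation_table(genes, tx, ex)
  res <- single_exon_fraction(ann)
  expect_equal(res$fraction, 0.25)
  expect_equal(res$k, 1)
  expect_error(single_exon_fraction(ann, group = "nope"),
               class = "gd_invalid_input")

  # recovery: zero exon rate forces every canonical transcript single-exon
  cfg0 <- sim_config(seed = 1, n_genes = 25,
                     exon_rate = c(epigene = 0, non_epigene = 0, histone = 0))
  expect_equal(single_exon_fraction(gen_annotation(cfg0))$fraction, 1)
})

test_that("regress_log fits OLS after log10 transforms", {
  x <- c(1, 10, 100, 1000)
  fit <- regress_log(x, 2 * x)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, log10(2), tolerance = 1e-12)

  set.seed(42)
  fit0 <- regress_log(rlnorm(10000), rlnorm(10000))
  expect_lt(fit0$r_squared, 0.01)

  expect_error(regress_log(c(1, 2), c(1, 2)), class = "gd_invalid_input")
  expect_error(regress_log(rep(2, 5), 1:5), class = "gd_invalid_input")
})

test_that("annotation_table enforces its invariants", {
  genes <- data.frame(gene_id = "g1", chromosome = "chr1", start = 1,
                      end = 1000, strand = "+")
  tx <- data.frame(transcript_id = c("t1", "t2"), gene_id = "g1",
                   canonical = c(TRUE, TRUE))
  ex <- data.frame(transcript_id = c("t1", "t2"), start = c(1, 1),
                   end = c(100, 100), rank = c(1, 1))
  expect_error(annotation_table(genes, tx, ex), class = "gd_invalid_input")
  tx$canonical <- c(TRUE, FALSE)
  expect_s3_class(annotation_table(genes, tx, ex), "annotation_table")
  ex$rank <- c(2, 1)
  expect_error(annotation_table(genes, tx, ex), class = "gd_invalid_input")
})
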