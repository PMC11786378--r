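# Isoform-usage diversity: within-sample Shannon entropy of isoform
# proportions and between-sample Kullback-Leibler divergence from the
# weighted mean profile, both averaged with combined sample weights.
# All logarithms are base 2 (bits).

#' Isoform expression tensor
#'
#' Non-negative isoform abundances (TPM) shared across a common sample set,
#' with a transcript-to-gene map; the substrate of the entropy/divergence
#' statistics.
#'
#' @param abund numeric matrix, transcripts x samples, non-negative, with
#'   row and column names.
#' @param map data.frame with transcript_id, gene_id covering all rows.
#' @return object of class `isoform_tensor`.
#' @export
isoform_tensor <- function(abund, map) {
  check_that(is.matrix(abund) && is.numeric(abund), "abund must be a numeric matrix")
  check_that(!is.null(rownames(abund)) && !is.null(colnames(abund)),
             "abund needs transcript row names and sample column names")
  check_that(all(is.finite(abund)) && all(abund >= 0),
             "abundances must be finite and non-negative")
  check_that(all(c("transcript_id", "gene_id") %in% names(map)),
             "map needs transcript_id and gene_id")
  check_that(!anyDuplicated(map$transcript_id), "duplicate transcript_id in map")
  check_that(setequal(rownames(abund), map$transcript_id),
             "map must cover exactly the abundance rows")
  map <- map[match(rownames(abund), map$transcript_id), ]
  structure(list(abund = abund, map = map,
                 genes = split(map$transcript_id, map$gene_id)),
            class = "isoform_tensor")
}

#' @export
print.isoform_tensor <- function(x, ...) {
  cat(sprintf("isoform_tensor: %d transcripts / %d genes x %d samples\n",
              nrow(x$abund), length(x$genes), ncol(x$abund)))
  invisible(x)
}

tensor_transcripts <- function(tensor, gene) {
  tx <- tensor$genes[[gene]]
  check_that(!is.null(tx), sprintf("unknown gene: %s", gene))
  tx
}

#' Isoform proportions of a gene in one sample
#'
#' @param tensor an [isoform_tensor].
#' @param gene gene id.
#' @param sample sample id.
#' @return named proportion vector summing to 1; a gene with zero total in
#'   the sample raises a classed `gd_unexpressed` condition.
#' @export
isoform_proportions <- function(tensor, gene, sample) {
  tx <- tensor_transcripts(tensor, gene)
  check_that(sample %in% colnames(tensor$abund),
             sprintf("unknown sample: %s", sample))
  a <- tensor$abund[tx, sample]
  total <- sum(a)
  if (total <= 0) {
    unexpressed_signal(sprintf("gene %s unexpressed in sample %s", gene, sample))
  }
  a / total
}

#' Shannon entropy of an isoform proportion vector, in bits
#'
#' `H = -sum_i x_i log2(x_i)` over the isoforms with non-zero proportion
#' (`0 * log 0 := 0`). Maximal (`log2 n`) for uniform use of n isoforms,
#' zero when a single isoform carries all expression.
#'
#' @param p proportion vector, non-negative, summing to 1.
#' @return entropy in bits.
#' @export
#' @examples
#' tissue_entropy(rep(0.25, 4)) # 2 bits
#' tissue_entropy(1) # 0 bits
tissue_entropy <- function(p) {
  check_that(all(p >= 0), "proportions must be non-negative")
  check_that(abs(sum(p) - 1) < 1e-6, "proportions must sum to 1")
  p <- p[p > 0]
  -sum(p * log2(p)) + 0 # + 0 normalizes IEEE -0 for the degenerate case
}

#' Effective number of isoforms implied by an entropy value
#'
#' `2^H`: the number of equally expressed isoforms with the same entropy.
#'
#' @param H entropy in bits, >= 0.
#' @return effective isoform count, >= 1.
#' @export
#' @examples
#' effective_isoform_count(2.1) # 4.3
effective_isoform_count <- function(H) {
  check_that(all(H >= 0), "entropy must be >= 0")
  2^H
}

# samples where the gene is expressed AND carries positive weight
expressed_weighted_samples <- function(tensor, tx, weights) {
  w <- weights[colnames(tensor$abund)]
  check_that(!any(is.na(w)), "weights must cover all tensor samples")
  totals <- colSums(tensor$abund[tx, , drop = FALSE])
  use <- totals > 0 & as.numeric(w) > 0
  if (!any(use)) {
    unexpressed_signal("gene has no expressed, positively weighted sample")
  }
  list(samples = colnames(tensor$abund)[use], w = as.numeric(w)[use])
}

require_multi_isoform <- function(tensor, gene) {
  tx <- tensor_transcripts(tensor, gene)
  if (length(tx) < 2) {
    excluded_input(sprintf("gene %s is annotated single-isoform; excluded", gene))
  }
  tx
}

#' Weighted mean intratissue entropy of a gene, in bits
#'
#' Weighted mean of the per-sample isoform entropies over samples where the
#' gene is expressed and has positive weight. Annotated single-isoform genes
#' are excluded (classed `gd_excluded_input` condition).
#'
#' @param tensor an [isoform_tensor].
#' @param gene gene id (>= 2 annotated isoforms).
#' @param weights named weights over samples (e.g. [combined_weights]);
#'   default uniform.
#' @return mean entropy in bits.
#' @export
mean_intratissue_entropy <- function(tensor, gene, weights = NULL) {
  tx <- require_multi_isoform(tensor, gene)
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, ncol(tensor$abund)), colnames(tensor$abund))
  }
  ew <- expressed_weighted_samples(tensor, tx, weights)
  H <- vapply(ew$samples,
              function(s) tissue_entropy(isoform_proportions(tensor, gene, s)),
              numeric(1))
  sum(ew$w * H) / sum(ew$w)
}

#' Weighted mean isoform profile of a gene
#'
#' `q_i = sum_t w_t x_(t,i) / sum_t w_t` over expressed, positively weighted
#' samples; isoforms never expressed in any such sample are dropped.
#'
#' @inheritParams mean_intratissue_entropy
#' @return named proportion vector q summing to 1.
#' @export
mean_profile <- function(tensor, gene, weights = NULL) {
  tx <- require_multi_isoform(tensor, gene)
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, ncol(tensor$abund)), colnames(tensor$abund))
  }
  ew <- expressed_weighted_samples(tensor, tx, weights)
  X <- vapply(ew$samples,
              function(s) isoform_proportions(tensor, gene, s),
              numeric(length(tx)))
  X <- matrix(X, nrow = length(tx),
              dimnames = list(tx, ew$samples)) # guard 1-isoform edge drop
  # keep isoforms expressed in at least one sample of the full set (a
  # zero-weight sample still counts toward "annotated and expressed")
  expressed <- rowSums(tensor$abund[tx, , drop = FALSE] > 0) > 0
  X <- X[expressed, , drop = FALSE]
  q <- as.numeric(X %*% ew$w) / sum(ew$w)
  stats::setNames(q, rownames(X))
}

#' Weighted mean intertissue divergence of a gene, in bits
#'
#' For each expressed, positively weighted sample, the Kullback-Leibler
#' divergence of the sample's isoform profile from the weighted mean profile
#' q: `D_t = sum_(i: x > 0) x_(t,i) log2(x_(t,i) / q_i)`; the reported value
#' is the weighted mean of D_t. Zero iff every such sample shares one
#' profile.
#'
#' @inheritParams mean_intratissue_entropy
#' @return mean divergence in bits, >= 0.
#' @export
mean_intertissue_divergence <- function(tensor, gene, weights = NULL) {
  tx <- require_multi_isoform(tensor, gene)
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, ncol(tensor$abund)), colnames(tensor$abund))
  }
  ew <- expressed_weighted_samples(tensor, tx, weights)
  q <- mean_profile(tensor, gene, weights)
  D <- vapply(ew$samples, function(s) {
    x <- isoform_proportions(tensor, gene, s)[names(q)]
    pos <- x > 0
    stopifnot(all(q[pos] > 0)) # x>0 with q=0 impossible by construction
    sum(x[pos] * log2(x[pos] / q[pos]))
  }, numeric(1))
  max(0, sum(ew$w * D) / sum(ew$w))
}

#' Per-gene diversity table
#'
#' Computes, for every gene of the tensor, the combined sample weights
#' (similarity x expression) and the weighted entropy/divergence summary.
#' Genes that are single-isoform, or unexpressed in every positively
#' weighted sample, are reported with `excluded = TRUE` and a reason.
#'
#' @param tensor an [isoform_tensor].
#' @param tree optional sample tree ([ape::phylo]); if `NULL` it is inferred
#'   with [cluster_samples] from the log-scale matrix; pass `NA` to use
#'   uniform similarity weights.
#' @return data.frame with gene_id, n_isoforms, mean_entropy_bits,
#'   effective_isoforms, mean_divergence_bits, excluded, reason.
#' @export
diversity_table <- function(tensor, tree = NULL) {
  tpm <- as_expr_matrix(tensor$abund, "tpm")
  eps <- median_normalize(log_transform(tpm))
  if (is.null(tree)) tree <- cluster_samples(unclass(eps))
  w_sim <- if (inherits(tree, "phylo")) similarity_weights(tree) else
    weight_vector(stats::setNames(rep(1, ncol(tensor$abund)),
                                  colnames(tensor$abund)), "similarity")
  check_that(setequal(names(w_sim), colnames(tensor$abund)),
             "tree tips must match tensor samples")

  rows <- lapply(names(tensor$genes), function(g) {
    tx <- tensor$genes[[g]]
    out <- data.frame(gene_id = g, n_isoforms = length(tx),
                      mean_entropy_bits = NA_real_,
                      effective_isoforms = NA_real_,
                      mean_divergence_bits = NA_real_,
                      excluded = FALSE, reason = "",
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      w_expr <- suppressWarnings(expression_weights(unclass(eps), tx))
      w <- combined_weights(w_sim, w_expr)
      H <- mean_intratissue_entropy(tensor, g, w)
      D <- mean_intertissue_divergence(tensor, g, w)
      list(H = H, D = D)
    },
    gd_excluded_input = function(e) conditionMessage(e),
    gd_unexpressed = function(e) conditionMessage(e))
    if (is.list(res)) {
      out$mean_entropy_bits <- res$H
      out$effective_isoforms <- effective_isoform_count(res$H)
      out$mean_divergence_bits <- res$D
    } else {
      out$excluded <- TRUE
      out$reason <- res
    }
    out
  })
  do.call(rbind, rows)
}
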