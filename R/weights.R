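# Sample weighting: a CLUSTALW-style similarity weight derived from the
# sample tree, a relative-expression weight per gene, and their product.
# These weights feed every downstream weighted statistic (entropy,
# divergence, Tau).

weight_vector <- function(w, provenance) {
  structure(w, provenance = provenance, class = c("weight_vector", "numeric"))
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("weights (%s):\n", attr(x, "provenance")))
  print(unclass(`attributes<-`(x, list(names = names(x)))))
  invisible(x)
}

#' Hierarchically cluster samples into a tree
#'
#' Agglomerative average-linkage clustering on distance 1 - Pearson
#' correlation between sample expression columns. Branch lengths are the
#' merge-height differences (clipped at zero).
#'
#' @param mat numeric matrix, features (genes or transcripts) x samples, with
#'   column names.
#' @return an [ape::phylo] tree whose tips are the sample names.
#' @export
cluster_samples <- function(mat) {
  check_that(is.matrix(mat) && ncol(mat) >= 2, "need a matrix with >= 2 samples")
  check_that(nrow(mat) >= 1, "need >= 1 feature row")
  check_that(!is.null(colnames(mat)), "samples must be named (column names)")
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) {
    gd_stop(sprintf("constant expression column(s): %s (correlation undefined)",
                    paste(colnames(mat)[sds == 0], collapse = ", ")),
            "gd_invalid_input")
  }
  d <- stats::as.dist(1 - stats::cor(mat))
  hc <- stats::hclust(d, method = "average")
  tree <- ape::as.phylo(hc)
  tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}

# number of descendant leaves below every node (tips included, = 1)
descendant_leaf_counts <- function(tree) {
  n_tip <- length(tree$tip.label)
  v <- integer(max(tree$edge))
  v[seq_len(n_tip)] <- 1L
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    v[po$edge[i, 1]] <- v[po$edge[i, 1]] + v[po$edge[i, 2]]
  }
  v
}

#' Tree-derived sample-set similarity weights
#'
#' Recursion over the rooted sample tree: `w(root) = 0` and for every other
#' node `w(t) = d(t, parent) / v(t) + w(parent)`, where `d` is the branch
#' length to the parent and `v(t)` the number of leaves descending from `t`.
#' Leaf weights are rescaled by the maximum leaf weight so the most isolated
#' sample has weight 1; duplicated (zero-distance) leaves share the weight a
#' single leaf would receive. Down-weights redundant, highly similar samples.
#'
#' @param tree rooted [ape::phylo] with branch lengths (>= 0). A single-tip
#'   tree, or a tree whose branch lengths are all zero, yields uniform
#'   weights of 1 (degenerate case).
#' @return named [weight_vector] over tip labels, provenance "similarity".
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:0,Adup:0):1,B:1,C:1);")
#' similarity_weights(tr) # A = Adup = 0.5, B = C = 1
similarity_weights <- function(tree) {
  check_that(inherits(tree, "phylo"), "tree must be an ape phylo object")
  n_tip <- length(tree$tip.label)
  if (n_tip == 1) {
    return(weight_vector(stats::setNames(1, tree$tip.label), "similarity"))
  }
  el <- tree$edge.length
  check_that(!is.null(el), "tree must have branch lengths")
  check_that(all(el >= 0), "branch lengths must be non-negative")
  if (all(el == 0)) {
    message("similarity_weights: all branch lengths zero; uniform weights")
    return(weight_vector(stats::setNames(rep(1, n_tip), tree$tip.label),
                         "similarity"))
  }
  v <- descendant_leaf_counts(tree)
  w <- numeric(max(tree$edge)) # root (and any unvisited) start at 0
  cw <- ape::reorder.phylo(tree, "cladewise") # parents before children
  for (i in seq_len(nrow(cw$edge))) {
    parent <- cw$edge[i, 1]; child <- cw$edge[i, 2]
    w[child] <- cw$edge.length[i] / v[child] + w[parent]
  }
  lw <- w[seq_len(n_tip)]
  lw <- lw / max(lw)
  weight_vector(stats::setNames(lw, tree$tip.label), "similarity")
}

#' Relative-expression weights for one gene
#'
#' The proportion of the gene's overall (median-normalized, log-scale)
#' expression in each sample relative to the maximum across samples:
#' `w2(t) = sum_i eps(t, i) / max_t' sum_i eps(t', i)`, summing over the
#' gene's isoforms. An everywhere-unexpressed gene yields an all-zero vector
#' and a classed warning (`gd_unexpressed_warning`); callers must exclude it.
#'
#' @param eps numeric matrix of median-normalized log10 expression,
#'   transcripts x samples (see [median_normalize]); or any non-negative
#'   expression matrix.
#' @param transcript_ids rows of `eps` belonging to the gene.
#' @return named [weight_vector] over samples, provenance "expression".
#' @export
expression_weights <- function(eps, transcript_ids) {
  check_that(is.matrix(eps) && !is.null(rownames(eps)) && !is.null(colnames(eps)),
             "eps must be a matrix with transcript row names and sample column names")
  missing_tx <- setdiff(transcript_ids, rownames(eps))
  check_that(length(missing_tx) == 0,
             paste("unknown transcript(s):", paste(missing_tx, collapse = ", ")))
  totals <- colSums(eps[transcript_ids, , drop = FALSE])
  check_that(all(totals >= 0), "expression values must be non-negative")
  if (max(totals) == 0) {
    warning(structure(
      class = c("gd_unexpressed_warning", "warning", "condition"),
      list(message = "gene unexpressed in every sample; all-zero weights",
           call = sys.call())))
    return(weight_vector(stats::setNames(rep(0, ncol(eps)), colnames(eps)),
                         "expression"))
  }
  weight_vector(stats::setNames(totals / max(totals), colnames(eps)),
                "expression")
}

#' Combined sample weights
#'
#' Elementwise product of the similarity and expression weights; the final
#' weight attributed to each biosample in the weighted statistics.
#'
#' @param w1,w2 [weight_vector]s over the same sample set (any order).
#' @return named [weight_vector], provenance "combined".
#' @export
combined_weights <- function(w1, w2) {
  check_that(!is.null(names(w1)) && !is.null(names(w2)),
             "weight vectors must be named")
  check_that(setequal(names(w1), names(w2)),
             "weight vectors cover different sample sets")
  w2 <- w2[names(w1)]
  weight_vector(stats::setNames(as.numeric(w1) * as.numeric(w2), names(w1)),
                "combined")
}
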