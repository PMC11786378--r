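# Expression normalization chain (raw -> tpm -> log -> median_normalized)
# and the weighted Tau specificity index. The median-normalized log10 matrix
# is the epsilon consumed by expression_weights().

expr_stage <- function(mat) attr(mat, "stage") %||% "raw"

set_stage <- function(mat, stage) {
  attr(mat, "stage") <- stage
  mat
}

#' Tag a matrix with its normalization stage
#'
#' @param mat numeric gene (or transcript) x sample matrix.
#' @param stage one of "raw", "tpm", "log", "median_normalized".
#' @return the matrix with a `stage` attribute; stage transitions are
#'   enforced in the documented order raw -> tpm -> log -> median_normalized.
#' @export
as_expr_matrix <- function(mat, stage = c("raw", "tpm", "log",
                                          "median_normalized")) {
  stage <- match.arg(stage)
  check_that(is.matrix(mat) && is.numeric(mat), "mat must be a numeric matrix")
  if (stage %in% c("raw", "tpm")) {
    check_that(all(mat >= 0), "abundances must be non-negative at raw/tpm stage")
  }
  set_stage(mat, stage)
}

require_stage <- function(mat, stage, op) {
  check_that(expr_stage(mat) == stage,
             sprintf("%s requires stage '%s' but matrix is at stage '%s'",
                     op, stage, expr_stage(mat)))
}

#' Filter to protein-coding, non-mitochondrial genes and renormalize to TPM
#'
#' @param mat raw-stage expression matrix with gene row names.
#' @param meta data.frame with gene_id, biotype, chromosome.
#' @return tpm-stage matrix; each sample column sums to 1e6.
#' @export
filter_and_renormalize <- function(mat, meta) {
  require_stage(mat, "raw", "filter_and_renormalize")
  check_that(all(c("gene_id", "biotype", "chromosome") %in% names(meta)),
             "meta needs gene_id, biotype, chromosome")
  keep_ids <- meta$gene_id[meta$biotype == "protein_coding" &
                             !(meta$chromosome %in% c("MT", "chrM", "chrMT"))]
  mat <- mat[rownames(mat) %in% keep_ids, , drop = FALSE]
  check_that(nrow(mat) > 0, "no protein-coding, non-mitochondrial genes left")
  totals <- colSums(mat)
  if (any(totals == 0)) {
    gd_stop(sprintf("sample(s) with zero total after filtering: %s",
                    paste(colnames(mat)[totals == 0], collapse = ", ")),
            "gd_invalid_input")
  }
  set_stage(sweep(mat, 2, totals, "/") * 1e6, "tpm")
}

#' log10(x + 1) transform
#'
#' @param mat tpm-stage matrix.
#' @return log-stage matrix; zeros stay zero.
#' @export
log_transform <- function(mat) {
  require_stage(mat, "tpm", "log_transform")
  set_stage(log10(mat + 1), "log")
}

#' Median normalization of log-scale expression
#'
#' Per sample, subtract the sample median over expressed genes (log value
#' > 0, i.e. nonzero raw abundance) and re-add the maximum of those sample
#' medians, centring every sample on a common median. Re-adding the max
#' (rather than the grand median) keeps all values non-negative, so the
#' negative-value clip never fires, and makes the offset invariant to
#' duplicating a sample — a property the downstream weighted statistics
#' rely on. Any clipped values are counted in the `n_clipped` attribute.
#'
#' @param mat log-stage matrix.
#' @return median_normalized-stage matrix.
#' @export
median_normalize <- function(mat) {
  require_stage(mat, "log", "median_normalize")
  meds <- apply(mat, 2, function(x) {
    xx <- x[x > 0]
    if (length(xx) == 0) 0 else stats::median(xx)
  })
  grand <- max(meds)
  out <- sweep(mat, 2, meds - grand, "-")
  n_clipped <- sum(out < 0 & mat > 0)
  out[out < 0] <- 0
  out <- set_stage(out, "median_normalized")
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Weighted Tau expression-specificity index
#'
#' Classic Tau is `sum_t (1 - xhat_t) / (m - 1)` with `xhat = x / max(x)`:
#' 0 for uniform expression, 1 for expression restricted to one of m
#' samples. The weighted variant replaces sample counts by sample-tree
#' similarity weights (rescaled to max 1): `sum_t w_t (1 - xhat_t) /
#' (sum_t w_t - 1)`. With uniform weights this reduces to classic Tau, and
#' duplicating a sample (whose pair of weights halve under the similarity
#' scheme) leaves the value unchanged.
#'
#' @param x non-negative expression vector over >= 2 samples (use the
#'   median-normalized log scale for comparability across genes).
#' @param w optional weights (default uniform); rescaled internally so
#'   max(w) = 1.
#' @return Tau in \[0, 1\].
#' @export
#' @examples
#' weighted_tau(c(10, 0, 0, 0)) # 1
#' weighted_tau(c(5, 5, 5, 5)) # 0
weighted_tau <- function(x, w = NULL) {
  m <- length(x)
  check_that(m >= 2, "need >= 2 samples")
  check_that(all(x >= 0), "expression must be non-negative")
  if (max(x) == 0) undefined_signal("all-zero expression vector: Tau undefined")
  if (is.null(w)) w <- rep(1, m)
  check_that(length(w) == m, "weights must match the expression vector")
  check_that(all(w >= 0) && sum(w) > 0, "weights must be >= 0 with positive sum")
  if (!is.null(names(w)) && !is.null(names(x))) {
    check_that(setequal(names(w), names(x)), "weight/sample name mismatch")
    w <- w[names(x)]
  }
  w <- as.numeric(w) / max(w)
  denom <- sum(w) - 1
  if (denom <= 0) {
    undefined_signal("effective sample count <= 1: Tau undefined")
  }
  xhat <- x / max(x)
  min(1, max(0, sum(w * (1 - xhat)) / denom))
}

#' Tau for every gene of an expression matrix
#'
#' @param mat median_normalized-stage matrix (genes x samples).
#' @param weights optional similarity [weight_vector] over samples.
#' @return data.frame (gene_id, tau); unexpressed genes get NA.
#' @export
specificity_table <- function(mat, weights = NULL) {
  if (!is.null(weights)) weights <- weights[colnames(mat)]
  tau <- apply(mat, 1, function(x) {
    if (max(x) == 0) return(NA_real_)
    weighted_tau(x, weights)
  })
  data.frame(gene_id = rownames(mat), tau = as.numeric(tau),
             stringsAsFactors = FALSE)
}
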