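# Independent brute-force oracles. Each is a deliberately naive
# re-derivation from first principles (plain loops, residue masks, a
# different library path), kept separate from the implementation it checks.

oracle_entropy <- function(p) {
  h <- 0
  for (x in p) if (x > 0) h <- h - x * log(x, base = 2)
  h
}

oracle_kl <- function(x, q) {
  d <- 0
  for (i in seq_along(x)) {
    if (x[i] > 0) d <- d + x[i] * log(x[i] / q[i], base = 2)
  }
  d
}

# weighted mean divergence for a small gene: proportions, q and KL all by
# explicit loops over a plain abundance matrix (isoforms x samples)
oracle_mean_divergence <- function(abund, w) {
  totals <- colSums(abund)
  use <- which(totals > 0 & w > 0)
  X <- sapply(use, function(s) abund[, s] / totals[s])
  X <- matrix(X, nrow = nrow(abund))
  keep <- rowSums(X) > 0
  X <- X[keep, , drop = FALSE]
  ww <- w[use]
  q <- as.numeric(X %*% ww) / sum(ww)
  D <- vapply(seq_along(use), function(j) oracle_kl(X[, j], q), numeric(1))
  sum(ww * D) / sum(ww)
}

# weighted Pearson via the independent stats::cov.wt path
oracle_wpearson <- function(x, y, w) {
  cw <- stats::cov.wt(cbind(x, y), wt = w / sum(w), method = "ML", cor = TRUE)
  cw$cor[1, 2]
}

# similarity weights by direct recursion over the edge matrix
oracle_similarity_weights <- function(tree) {
  n <- length(tree$tip.label)
  tips_under <- function(node) {
    if (node <= n) return(1L)
    sum(vapply(tree$edge[tree$edge[, 1] == node, 2], tips_under, integer(1)))
  }
  rec <- function(node, w) {
    if (node <= n) return(stats::setNames(w, tree$tip.label[node]))
    unlist(lapply(which(tree$edge[, 1] == node), function(k) {
      child <- tree$edge[k, 2]
      rec(child, w + tree$edge.length[k] / tips_under(child))
    }))
  }
  lw <- rec(n + 1L, 0)
  lw <- lw[tree$tip.label]
  if (max(lw) == 0) lw[] <- 1 else lw <- lw / max(lw)
  lw
}

# interval merging via a residue occupancy mask
oracle_merge <- function(intervals, len) {
  mask <- logical(len)
  for (i in seq_len(nrow(intervals))) {
    mask[intervals$start[i]:intervals$end[i]] <- TRUE
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

oracle_tau <- function(x, w) {
  w <- w / max(w)
  xhat <- x / max(x)
  sum(w * (1 - xhat)) / (sum(w) - 1)
}
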