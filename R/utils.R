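#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' used to score recovery of planted cluster/class structure.
#'
#' @param a,b vectors of labels of equal length.
#' @return Adjusted Rand index in \[-1, 1\]; 1 for identical partitions.
#' @export
#' @examples
#' adjusted_rand(c(1, 1, 2, 2), c("x", "x", "y", "y")) # 1
adjusted_rand <- function(a, b) {
  check_that(length(a) == length(b) && length(a) >= 2,
             "a and b must be equal-length vectors of length >= 2")
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1) # both partitions trivial
  (sij - expected) / (maxi - expected)
}

# Dirichlet draw by gamma normalization. Degenerate all-zero draws (possible
# for very small shapes) collapse to a point mass at the largest shape.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(g)
  if (s <= 0 || !is.finite(s)) {
    out <- numeric(length(alpha))
    out[which.max(alpha)] <- 1
    return(out)
  }
  g / s
}

# random integer composition of `total` into k parts, each >= minimum
rcomposition <- function(total, k, minimum = 0L) {
  free <- total - k * minimum
  stopifnot(free >= 0)
  if (k == 1L) return(total)
  if (free == 0L) return(rep(minimum, k))
  parts <- as.vector(stats::rmultinom(1, free, rep(1, k)))
  parts + minimum
}

`%||%` <- function(x, y) if (is.null(x)) y else x
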