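#' Geometric mean
#'
#' Central tendency on the log scale, used wherever a feature distribution is
#' approximately log-normal (gene lengths, isoform counts, partner counts).
#' Zeros are excluded before averaging and their count is reported via a
#' warning and the `n_zero_excluded` attribute.
#'
#' @param x numeric vector, values >= 0 (zeros excluded, negatives rejected).
#' @return the geometric mean `exp(mean(log(x)))` of the positive values.
#' @export
#' @examples
#' geometric_mean(c(1, 100)) # 10
geometric_mean <- function(x) {
  check_that(is.numeric(x), "x must be numeric")
  x <- x[!is.na(x)]
  check_that(all(x >= 0), "x must be non-negative")
  n_zero <- sum(x == 0)
  x <- x[x > 0]
  check_that(length(x) > 0, "no positive values to average")
  if (n_zero > 0) {
    warning(sprintf("geometric_mean: excluded %d zero value(s)", n_zero))
  }
  structure(exp(mean(log(x))), n_zero_excluded = n_zero)
}

# named statistic aggregators available to permutation tests
stat_aggregators <- function(threshold = NULL) {
  list(
    mean = mean,
    geometric_mean = function(v) as.numeric(geometric_mean(v)),
    median = stats::median,
    proportion_above = function(v) {
      check_that(!is.null(threshold), "threshold required for proportion_above")
      mean(v > threshold)
    }
  )
}

#' Group-contrast permutation test by resampling the background pool
#'
#' The null distribution is built by repeatedly sampling, without
#' replacement, a contrast set from the non-focal pool equal in size to the
#' focal group and recomputing the statistic. One-sided p-values use the
#' add-one convention, clamped below at the reportable floor `1/n_perm`;
#' when no resample is as extreme as the observed statistic the result is
#' flagged `saturated` and displayed as `< 1/n_perm`.
#'
#' @param values numeric per-gene feature values.
#' @param labels group label per value (two or more levels; everything that
#'   is not `focal` forms the resampling pool).
#' @param focal label of the focal group; default the first level present.
#' @param statistic aggregator name: one of `"mean"`, `"geometric_mean"`,
#'   `"median"`, `"proportion_above"`; or a function.
#' @param n_perm number of resampled contrast sets.
#' @param seed optional integer seed for reproducibility.
#' @param sided `"two"`, `"upper"` or `"lower"`.
#' @param threshold cut point for the `proportion_above` aggregator.
#' @param keep_null keep the null sample in the result (default TRUE).
#' @return object of class `permutation_test`: observed statistic, one- and
#'   two-sided p-values, floor, saturation flag, and the null sample.
#' @export
#' @examples
#' set.seed(1)
#' v <- c(rnorm(20, 2), rnorm(50))
#' permutation_test(v, rep(c("focal", "pool"), c(20, 50)),
#'                  n_perm = 200, seed = 1)
permutation_test <- function(values, labels, focal = NULL,
                             statistic = "mean", n_perm = 1000, seed = NULL,
                             sided = c("two", "upper", "lower"),
                             threshold = NULL, keep_null = TRUE) {
  sided <- match.arg(sided)
  check_that(length(values) == length(labels),
             "values and labels must have equal length")
  check_that(n_perm >= 1, "n_perm must be >= 1")
  keep <- !is.na(values)
  values <- values[keep]; labels <- as.character(labels)[keep]
  if (is.null(focal)) focal <- labels[1]
  focal_vals <- values[labels == focal]
  pool_vals <- values[labels != focal]
  check_that(length(focal_vals) > 0, "focal group is empty")
  check_that(length(pool_vals) > 0, "contrast pool is empty")
  k <- length(focal_vals)
  check_that(length(pool_vals) >= k,
             "contrast pool smaller than the focal group")

  if (is.function(statistic)) {
    fn <- statistic
    stat_name <- "custom"
  } else {
    aggs <- stat_aggregators(threshold)
    check_that(statistic %in% names(aggs),
               paste("unknown statistic:", statistic))
    fn <- aggs[[statistic]]
    stat_name <- statistic
  }

  observed <- fn(focal_vals)
  if (!is.null(seed)) set.seed(seed)
  null_stats <- vapply(seq_len(n_perm),
                       function(i) fn(sample(pool_vals, k)),
                       numeric(1))

  floor_p <- 1 / n_perm
  n_ge <- sum(null_stats >= observed)
  n_le <- sum(null_stats <= observed)
  p_up <- max(floor_p, (1 + n_ge) / (1 + n_perm))
  p_lo <- max(floor_p, (1 + n_le) / (1 + n_perm))
  p_one <- switch(sided, upper = p_up, lower = p_lo, two = min(p_up, p_lo))
  saturated <- switch(sided, upper = n_ge == 0, lower = n_le == 0,
                      two = min(n_ge, n_le) == 0)

  structure(list(
    observed = observed,
    null = if (keep_null) null_stats else NULL,
    p_one_sided = p_one,
    p_two_sided = min(1, 2 * p_one),
    n_perm = n_perm,
    floor = floor_p,
    saturated = saturated,
    display = if (saturated) paste0("< ", format(floor_p)) else format(p_one),
    statistic = stat_name,
    focal = focal,
    n_focal = k,
    sided = sided,
    seed = seed
  ), class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf(
    "Permutation test (%s, %s-sided): observed = %.4g, p_one_sided %s%s\n",
    x$statistic, x$sided, x$observed,
    if (x$saturated) x$display else format(x$p_one_sided),
    sprintf(" (n_perm = %d, floor = %g)", x$n_perm, x$floor)))
  invisible(x)
}

#' Two-sample test of proportions
#'
#' Chi-square (z) test for equality of two binomial proportions, without
#' continuity correction, so identical proportions give p = 1 exactly.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @return two-sided p-value in (0, 1].
#' @export
#' @examples
#' proportion_test(50, 100, 50, 100) # 1
proportion_test <- function(k1, n1, k2, n2) {
  check_that(n1 > 0 && n2 > 0, "n1 and n2 must be positive")
  check_that(k1 >= 0 && k1 <= n1 && k2 >= 0 && k2 <= n2,
             "k must satisfy 0 <= k <= n")
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  if (pp == 0 || pp == 1) return(1) # both groups degenerate and equal
  z2 <- (p1 - p2)^2 / (pp * (1 - pp) * (1 / n1 + 1 / n2))
  stats::pchisq(z2, df = 1, lower.tail = FALSE)
}

#' Bonferroni adjustment
#'
#' @param p numeric vector of p-values.
#' @param m number of tests corrected for; must be at least `length(p)`.
#' @return `pmin(1, m * p)`.
#' @export
bonferroni <- function(p, m = length(p)) {
  check_that(m >= length(p), "m must be >= number of p-values")
  check_that(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must lie in [0,1]")
  pmin(1, m * p)
}
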