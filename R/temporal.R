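# Temporal co-expression clustering of developmental (BrainSpan-style)
# expression: per-subregion preparation, range filtering, max scaling,
# log-scale time-bin weights, weighted Pearson correlation, average-linkage
# clustering of seed genes, assignment of the remaining genes, and
# cross-subregion metaclustering. Fully deterministic given its inputs.

#' Prepare per-subregion temporal profiles
#'
#' Samples of the same age within a subregion are averaged first, then each
#' age column is converted to TPM (column rescaled to 1e6). Ages above
#' `max_age` pcw are dropped, and subregions sampled at fewer than
#' `min_timepoints` ages are discarded.
#'
#' @param samples long-format data.frame with subregion, age_pcw, gene,
#'   value (RPKM).
#' @param min_timepoints minimum distinct ages per retained subregion.
#' @param max_age oldest age retained, in post-conception weeks.
#' @return named list of profiles: each a list with subregion, ages
#'   (strictly increasing pcw), mat (gene x age TPM matrix), units.
#' @export
prepare_profiles <- function(samples, min_timepoints = 5, max_age = 40) {
  check_that(all(c("subregion", "age_pcw", "gene", "value") %in% names(samples)),
             "samples needs subregion, age_pcw, gene, value")
  check_that(all(samples$value >= 0), "expression values must be non-negative")
  samples <- samples[samples$age_pcw <= max_age, , drop = FALSE]
  out <- lapply(split(samples, samples$subregion), function(df) {
    ages <- sort(unique(df$age_pcw))
    if (length(ages) < min_timepoints) return(NULL)
    genes <- sort(unique(df$gene))
    mat <- matrix(0, length(genes), length(ages),
                  dimnames = list(genes, as.character(ages)))
    # average same-age samples, then rescale each age column to TPM
    agg <- stats::aggregate(value ~ gene + age_pcw, df, mean)
    mat[cbind(match(agg$gene, genes), match(agg$age_pcw, ages))] <- agg$value
    totals <- colSums(mat)
    check_that(all(totals > 0), "age column with zero total expression")
    mat <- sweep(mat, 2, totals, "/") * 1e6
    list(subregion = df$subregion[1], ages = ages, mat = mat, units = "TPM")
  })
  out[!vapply(out, is.null, logical(1))]
}

#' Drop genes with minimal temporal variation
#'
#' Genes whose temporal expression range (max - min) is strictly below
#' `min_range` are removed.
#'
#' @param profile a profile from [prepare_profiles].
#' @param min_range exclusion threshold on the range.
#' @return the profile with a filtered matrix and a `dropped` element.
#' @export
filter_by_range <- function(profile, min_range = 0.5) {
  rng <- apply(profile$mat, 1, function(x) max(x) - min(x))
  keep <- rng >= min_range
  profile$dropped <- rownames(profile$mat)[!keep]
  profile$mat <- profile$mat[keep, , drop = FALSE]
  profile
}

#' Scale each gene to unit maximum
#'
#' @param profile a range-filtered profile.
#' @return the profile with each retained gene divided by its maximum
#'   (units tag "scaled").
#' @export
scale_max <- function(profile) {
  check_that(all(profile$mat >= 0), "negative expression cannot be max-scaled")
  mx <- apply(profile$mat, 1, max)
  stopifnot(all(mx > 0)) # guaranteed after range filtering
  profile$mat <- profile$mat / mx
  profile$units <- "scaled"
  profile
}

#' Developmental time-bin weights
#'
#' Ages are grouped into bins spanning `bin_width` weeks from conception to
#' `max_age` (default four 10-week bins, week 0 to 40). Each non-empty bin
#' receives equal total weight, split equally among its ages, correcting for
#' uneven sampling across development. Weights sum to 1.
#'
#' @param ages post-conception weeks, in (0, max_age].
#' @param bin_width,max_age bin geometry in weeks.
#' @return named weight per age.
#' @export
#' @examples
#' binned_time_weights(c(8, 9, 38)) # 0.25, 0.25, 0.5
binned_time_weights <- function(ages, bin_width = 10, max_age = 40) {
  check_that(all(ages > 0 & ages <= max_age),
             sprintf("ages must lie in (0, %g]", max_age))
  breaks <- seq(0, max_age, by = bin_width)
  bin <- findInterval(ages, breaks, left.open = TRUE) # (0,10], (10,20], ...
  n_in_bin <- table(bin)
  n_nonempty <- length(n_in_bin)
  w <- 1 / (n_nonempty * as.numeric(n_in_bin[as.character(bin)]))
  stats::setNames(w, as.character(ages))
}

#' Weighted Pearson correlation
#'
#' Weighted covariance over the product of weighted standard deviations;
#' with uniform weights this is the ordinary Pearson correlation.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @param w non-negative weights with positive sum (default uniform).
#' @return correlation in \[-1, 1\]; zero weighted variance in either vector
#'   raises a classed `gd_undefined` condition.
#' @export
weighted_pearson <- function(x, y, w = NULL) {
  n <- length(x)
  check_that(n >= 2 && length(y) == n, "x and y must have equal length >= 2")
  if (is.null(w)) w <- rep(1, n)
  check_that(length(w) == n && all(w >= 0) && sum(w) > 0,
             "weights must be non-negative with positive sum")
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx <= 0 || vy <= 0) {
    undefined_signal("zero weighted variance: correlation undefined")
  }
  cv <- sum(w * (x - mx) * (y - my))
  min(1, max(-1, cv / sqrt(vx * vy)))
}

cluster_means <- function(mat, membership) {
  ids <- sort(unique(membership))
  means <- t(vapply(ids, function(k)
    colMeans(mat[names(membership)[membership == k], , drop = FALSE]),
    numeric(ncol(mat))))
  rownames(means) <- as.character(ids)
  means
}

#' Cluster seed genes on their temporal trajectories
#'
#' Average-linkage agglomeration on distance 1 - weighted Pearson
#' correlation between scaled trajectories, cut at `cut` (default 0.2, i.e.
#' within-cluster correlation of roughly >= 0.8).
#'
#' @param profile a scaled profile (see [scale_max]).
#' @param seed_genes genes to cluster (>= 2 present in the profile).
#' @param weights per-age weights (default [binned_time_weights] on the
#'   profile ages).
#' @param cut tree-cut height on the 1 - correlation scale.
#' @return a `cluster_set`: subregion, ages, membership (named integer
#'   vector over seed genes), means (cluster x age matrix), assigned
#'   (initially empty), weights, cut.
#' @export
cluster_seed_genes <- function(profile, seed_genes, weights = NULL,
                               cut = 0.2) {
  seed_genes <- intersect(seed_genes, rownames(profile$mat))
  check_that(length(seed_genes) >= 2, "need >= 2 seed genes in the profile")
  if (is.null(weights)) weights <- binned_time_weights(profile$ages)
  m <- profile$mat[seed_genes, , drop = FALSE]
  n <- nrow(m)
  dmat <- matrix(0, n, n, dimnames = list(seed_genes, seed_genes))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- tryCatch(weighted_pearson(m[i, ], m[j, ], weights),
                    gd_undefined = function(e) 0)
      dmat[i, j] <- dmat[j, i] <- 1 - r
    }
  }
  hc <- stats::hclust(stats::as.dist(dmat), method = "average")
  membership <- stats::cutree(hc, h = cut)
  structure(list(subregion = profile$subregion, ages = profile$ages,
                 membership = membership,
                 means = cluster_means(m, membership),
                 assigned = data.frame(gene = character(0),
                                       cluster = integer(0),
                                       correlation = numeric(0)),
                 weights = weights, cut = cut),
            class = "cluster_set")
}

#' Assign non-seed genes to the best-matching cluster
#'
#' Each gene is assigned to the cluster whose mean trajectory it correlates
#' with most strongly, provided that correlation strictly exceeds
#' `threshold`; otherwise it is left unassigned. Ties break to the lowest
#' cluster id.
#'
#' @param clusters a `cluster_set` from [cluster_seed_genes].
#' @param profile the scaled profile the genes live in.
#' @param genes genes to assign (default: all non-seed genes in the profile).
#' @param threshold assignment correlation threshold (strict >).
#' @return the `cluster_set` with the `assigned` table filled in.
#' @export
assign_genes <- function(clusters, profile, genes = NULL, threshold = 0.8) {
  if (is.null(genes)) {
    genes <- setdiff(rownames(profile$mat), names(clusters$membership))
  }
  genes <- intersect(genes, rownames(profile$mat))
  rows <- lapply(genes, function(g) {
    r <- vapply(rownames(clusters$means), function(k) {
      tryCatch(weighted_pearson(profile$mat[g, ], clusters$means[k, ],
                                clusters$weights),
               gd_undefined = function(e) -Inf)
    }, numeric(1))
    best <- which.max(r) # ties: first index = lowest cluster id
    if (r[best] > threshold) {
      data.frame(gene = g, cluster = as.integer(rownames(clusters$means)[best]),
                 correlation = unname(r[best]), stringsAsFactors = FALSE)
    } else NULL
  })
  clusters$assigned <- do.call(rbind, c(rows,
    list(data.frame(gene = character(0), cluster = integer(0),
                    correlation = numeric(0)))))
  clusters
}

#' Nearest-timepoint imputation onto a target age grid
#'
#' @param values trajectory values observed at `ages`.
#' @param ages strictly increasing observed ages.
#' @param target ages to impute onto; exact matches pass through, otherwise
#'   the value at the nearest observed age is used, ties resolving to the
#'   earlier age.
#' @return values on the target grid.
#' @export
impute_nearest <- function(values, ages, target) {
  check_that(length(ages) >= 1 && length(values) == length(ages),
             "values and ages must be non-empty and matched")
  check_that(!is.unsorted(ages, strictly = TRUE), "ages must be strictly increasing")
  idx <- vapply(target, function(b) which.min(abs(ages - b)), integer(1))
  stats::setNames(values[idx], as.character(target))
}

#' Metacluster tissue clusters across subregions
#'
#' Cluster mean trajectories are imputed onto the union age grid
#' (nearest-timepoint rule), then average-linkage clustered on
#' 1 - weighted Pearson with time-bin weights on the union grid, cut at
#' `cut`.
#'
#' @param cluster_sets list of `cluster_set`s (>= 2 tissue clusters in
#'   total).
#' @param cut tree-cut height on the 1 - correlation scale.
#' @return data.frame with subregion, cluster, metacluster.
#' @export
metacluster <- function(cluster_sets, cut = 0.2) {
  entries <- do.call(rbind, lapply(cluster_sets, function(cs) {
    data.frame(subregion = cs$subregion,
               cluster = as.integer(rownames(cs$means)),
               stringsAsFactors = FALSE)
  }))
  check_that(!is.null(entries) && nrow(entries) >= 2,
             "need >= 2 tissue clusters to metacluster")
  union_ages <- sort(unique(unlist(lapply(cluster_sets, `[[`, "ages"))))
  w <- binned_time_weights(union_ages)
  traj <- t(mapply(function(sr, cl) {
    cs <- Filter(function(z) z$subregion == sr, cluster_sets)[[1]]
    impute_nearest(cs$means[as.character(cl), ], cs$ages, union_ages)
  }, entries$subregion, entries$cluster))
  n <- nrow(traj)
  dmat <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- tryCatch(weighted_pearson(traj[i, ], traj[j, ], w),
                    gd_undefined = function(e) 0)
      dmat[i, j] <- dmat[j, i] <- 1 - r
    }
  }
  hc <- stats::hclust(stats::as.dist(dmat), method = "average")
  entries$metacluster <- as.integer(stats::cutree(hc, h = cut))
  rownames(entries) <- NULL
  entries
}
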