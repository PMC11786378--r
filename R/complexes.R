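# Protein-complex partner counting. A "distinct complex" is a distinct
# curated complex id (two ids with identical membership count as two). A
# partner of a gene is any other member of any of the gene's complexes;
# constitutive if present in every one of the gene's complexes, variable
# otherwise.

#' Complex membership table
#'
#' @param members named list: complex id -> character vector of member ids.
#'   Duplicate member entries within a complex are collapsed.
#' @return object of class `complex_table`.
#' @export
complex_table <- function(members) {
  check_that(is.list(members) && length(names(members)) == length(members) &&
               !anyDuplicated(names(members)),
             "members must be a list with unique complex ids as names")
  members <- lapply(members, function(m) unique(as.character(m)))
  check_that(all(lengths(members) >= 1), "member sets must be non-empty")
  structure(list(members = members), class = "complex_table")
}

#' @export
print.complex_table <- function(x, ...) {
  cat(sprintf("complex_table: %d complexes, %d distinct members\n",
              length(x$members), length(unique(unlist(x$members)))))
  invisible(x)
}

#' The KAT6A worked example
#'
#' KAT6A participates in three curated complexes, each containing ING5 and
#' MEAF6 (constitutive partners) and distinguished by the BRPF species
#' (BRPF1/2/3, the variable partners).
#'
#' @return a [complex_table] with the three KAT6A complexes.
#' @export
kat6a_complex_table <- function() {
  complex_table(list(
    "CPX-KAT6A-BRPF1" = c("KAT6A", "ING5", "MEAF6", "BRPF1"),
    "CPX-KAT6A-BRPF2" = c("KAT6A", "ING5", "MEAF6", "BRPF2"),
    "CPX-KAT6A-BRPF3" = c("KAT6A", "ING5", "MEAF6", "BRPF3")
  ))
}

#' Complexes containing a gene
#'
#' @param table a [complex_table].
#' @param gene gene/protein id.
#' @return character vector of complex ids (possibly empty).
#' @export
complexes_of <- function(table, gene) {
  names(table$members)[vapply(table$members, function(m) gene %in% m,
                              logical(1))]
}

#' Mean number of distinct proteins in a gene's complexes
#'
#' @inheritParams complexes_of
#' @return arithmetic mean of member-set sizes; a gene in no complex raises
#'   a classed `gd_excluded_input` condition.
#' @export
mean_complex_size <- function(table, gene) {
  ids <- complexes_of(table, gene)
  if (length(ids) == 0) {
    excluded_input(sprintf("gene %s is in no complex", gene))
  }
  mean(lengths(table$members[ids]))
}

#' Constitutive and variable binding partners of a gene
#'
#' Requires membership in at least two complexes (genes with one or fewer
#' are excluded from the variable-partner comparison). Partners are the
#' union of non-self members across the gene's complexes; constitutive
#' partners appear in every complex, the rest are variable.
#'
#' @inheritParams complexes_of
#' @return list with n_variable, n_constitutive, variable, constitutive,
#'   n_complexes.
#' @export
#' @examples
#' variable_partners(kat6a_complex_table(), "KAT6A")
variable_partners <- function(table, gene) {
  ids <- complexes_of(table, gene)
  if (length(ids) < 2) {
    excluded_input(sprintf("gene %s is in %d complex(es); need >= 2",
                           gene, length(ids)))
  }
  sets <- lapply(table$members[ids], setdiff, y = gene)
  all_partners <- sort(unique(unlist(sets)))
  constitutive <- all_partners[vapply(all_partners, function(p)
    all(vapply(sets, function(s) p %in% s, logical(1))), logical(1))]
  variable <- setdiff(all_partners, constitutive)
  list(n_variable = length(variable),
       n_constitutive = length(constitutive),
       variable = variable, constitutive = constitutive,
       n_complexes = length(ids))
}

#' Per-group complex summary
#'
#' For each gene with a label: number of complexes, mean complex size,
#' variable-partner count (NA when the gene is in fewer than two
#' complexes), plus per-group association fractions and eCDF functions of
#' the complex counts. Feeds the group-contrast tests.
#'
#' @param table a [complex_table].
#' @param labels data.frame with gene_id, group.
#' @return list with `genes` (per-gene data.frame) and `groups` (per-group
#'   list: n, fraction_in_complex, ecdf_n_complexes).
#' @export
complex_summary <- function(table, labels) {
  check_that(all(c("gene_id", "group") %in% names(labels)),
             "labels needs gene_id and group")
  per_gene <- do.call(rbind, lapply(seq_len(nrow(labels)), function(i) {
    g <- labels$gene_id[i]
    ids <- complexes_of(table, g)
    nv <- if (length(ids) >= 2) variable_partners(table, g)$n_variable else NA_integer_
    data.frame(gene_id = g, group = labels$group[i],
               n_complexes = length(ids),
               mean_complex_size = if (length(ids) >= 1)
                 mean_complex_size(table, g) else NA_real_,
               n_variable_partners = nv, stringsAsFactors = FALSE)
  }))
  groups <- lapply(split(per_gene, per_gene$group), function(df) {
    list(n = nrow(df),
         fraction_in_complex = mean(df$n_complexes >= 1),
         ecdf_n_complexes = if (any(df$n_complexes >= 1))
           stats::ecdf(df$n_complexes[df$n_complexes >= 1]) else NULL)
  })
  list(genes = per_gene, groups = groups)
}
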