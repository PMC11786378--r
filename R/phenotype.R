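# Ontology-based phenotype-system mapping. Diseases annotated with
# fine-grained phenotype terms are mapped, by ancestor closure over the
# term DAG, to "major body systems": the direct children of the designated
# root phenotypic-abnormality term.

#' Phenotype ontology graph
#'
#' A single-rooted DAG of terms given as child -> parent edges. Multi-parent
#' terms are allowed (HPO-style); cycles and unreachable terms are rejected.
#'
#' @param edges data.frame with columns child, parent.
#' @param root optional root term id; inferred as the unique parentless term
#'   when omitted.
#' @return object of class `ontology_graph` with memoized ancestor lookup.
#' @export
ontology_graph <- function(edges, root = NULL) {
  check_that(all(c("child", "parent") %in% names(edges)),
             "edges needs child and parent columns")
  edges$child <- as.character(edges$child)
  edges$parent <- as.character(edges$parent)
  terms <- unique(c(edges$child, edges$parent))
  parents <- split(edges$parent, edges$child)
  roots <- setdiff(terms, edges$child)
  if (is.null(root)) {
    check_that(length(roots) == 1,
               sprintf("ontology must have exactly one root (found %d)",
                       length(roots)))
    root <- roots
  } else {
    check_that(root %in% terms, "designated root not present in the ontology")
    check_that(all(roots == root),
               "terms exist that do not reach the designated root")
  }
  # cycle check: Kahn-style peeling by parent resolution
  state <- new.env(parent = emptyenv())
  anc <- function(term, stack = character(0)) {
    if (term %in% stack) {
      gd_stop(sprintf("ontology cycle involving term %s", term),
              "gd_invalid_input")
    }
    cached <- state[[term]]
    if (!is.null(cached)) return(cached)
    ps <- parents[[term]]
    out <- if (is.null(ps)) character(0) else
      unique(c(ps, unlist(lapply(ps, anc, stack = c(stack, term)))))
    state[[term]] <- out
    out
  }
  for (t in terms) anc(t) # validates acyclicity, fills the memo
  check_that(all(vapply(setdiff(terms, root),
                        function(t) root %in% state[[t]], logical(1))),
             "every term must reach the root")
  structure(list(edges = edges, terms = terms, root = root,
                 children = split(edges$child, edges$parent),
                 ancestors = state),
            class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("ontology_graph: %d terms, root = %s, %d major systems\n",
              length(x$terms), x$root, length(major_systems(x))))
  invisible(x)
}

#' Ancestors of a term (excluding the term itself)
#'
#' @param graph an [ontology_graph].
#' @param term term id.
#' @return character vector of ancestor term ids.
#' @export
term_ancestors <- function(graph, term) {
  check_that(term %in% graph$terms, sprintf("unknown term: %s", term))
  graph$ancestors[[term]] %||% character(0)
}

#' Major body systems: direct children of the root phenotype term
#'
#' @param graph an [ontology_graph].
#' @return character vector of system term ids.
#' @export
major_systems <- function(graph) {
  sort(unique(graph$children[[graph$root]]))
}

#' Map phenotype terms to the major systems they fall under
#'
#' Union over terms of (ancestors plus the term itself) intersected with the
#' major systems; a term that *is* a system term counts for that system.
#'
#' @param graph an [ontology_graph].
#' @param terms character vector of term ids (all must be in the graph).
#' @return character vector of system ids (subset of [major_systems]).
#' @export
map_terms_to_systems <- function(graph, terms) {
  unknown <- setdiff(terms, graph$terms)
  check_that(length(unknown) == 0,
             paste("unknown term(s):", paste(unknown, collapse = ", ")))
  systems <- major_systems(graph)
  hits <- lapply(terms, function(t) intersect(c(t, term_ancestors(graph, t)),
                                              systems))
  sort(unique(unlist(hits)))
}

known_other_modes <- paste("other|multifactorial|mitochondrial|x-linked",
                           "y-linked|digenic|isolated|somatic", sep = "|")

normalize_inheritance <- function(modes) {
  m <- tolower(trimws(modes))
  out <- ifelse(grepl("dominant", m), "dominant",
                ifelse(grepl("recessive", m), "recessive", "other"))
  unknown <- m[!grepl(paste("dominant|recessive", known_other_modes,
                            sep = "|"), m) & nzchar(m)]
  if (length(unknown) > 0) {
    warning(sprintf("unrecognized inheritance mode(s) mapped to 'other': %s",
                    paste(unique(unknown), collapse = ", ")))
  }
  out
}

#' Filter disease annotations to germline, non-susceptibility records
#'
#' Removes diseases flagged as arising from somatic mutations and genes
#' associated as susceptibility factors; removal counts are reported in
#' attributes `n_somatic_removed` / `n_susceptibility_removed`.
#'
#' @param annotations data.frame with gene_id, disease_id, modes
#'   (semicolon-separated), somatic, susceptibility, terms
#'   (semicolon-separated term ids).
#' @return filtered annotations.
#' @export
filter_diseases <- function(annotations) {
  check_that(all(c("gene_id", "disease_id", "somatic", "susceptibility")
                 %in% names(annotations)),
             "annotations needs gene_id, disease_id, somatic, susceptibility")
  som <- as.logical(annotations$somatic)
  sus <- as.logical(annotations$susceptibility)
  out <- annotations[!som & !sus, , drop = FALSE]
  attr(out, "n_somatic_removed") <- sum(som)
  attr(out, "n_susceptibility_removed") <- sum(sus & !som)
  out
}

split_field <- function(x) strsplit(as.character(x), ";", fixed = TRUE)

#' Major systems affected per gene
#'
#' Union of the system sets of a gene's (filtered) diseases; genes with no
#' retained disease are absent from the output.
#'
#' @param graph an [ontology_graph].
#' @param annotations filtered disease annotations (see [filter_diseases])
#'   with a `terms` column of semicolon-separated term ids.
#' @return data.frame with gene_id, n_systems, systems
#'   (semicolon-separated).
#' @export
systems_per_gene <- function(graph, annotations) {
  check_that("terms" %in% names(annotations), "annotations needs a terms column")
  term_lists <- split_field(annotations$terms)
  by_gene <- split(term_lists, annotations$gene_id)
  rows <- lapply(names(by_gene), function(g) {
    sys <- map_terms_to_systems(graph, unique(unlist(by_gene[[g]])))
    data.frame(gene_id = g, n_systems = length(sys),
               systems = paste(sys, collapse = ";"), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-gene inheritance flags
#'
#' ORs the (normalized) inheritance modes over each gene's diseases; a gene
#' may be flagged both dominant and recessive.
#'
#' @param annotations filtered disease annotations with a `modes` column of
#'   semicolon-separated mode strings.
#' @return data.frame with gene_id, any_dominant, any_recessive.
#' @export
inheritance_summary <- function(annotations) {
  check_that("modes" %in% names(annotations), "annotations needs a modes column")
  mode_lists <- lapply(split_field(annotations$modes), normalize_inheritance)
  by_gene <- split(mode_lists, annotations$gene_id)
  rows <- lapply(names(by_gene), function(g) {
    modes <- unlist(by_gene[[g]])
    data.frame(gene_id = g,
               any_dominant = "dominant" %in% modes,
               any_recessive = "recessive" %in% modes,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
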