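# Readers and writers for the plain-text dialects the pipeline exchanges:
# BioMart-style annotation TSV (or GTF via rtracklayer), transcript x sample
# matrix + transcript-to-gene map, Complex-Portal-style complex table,
# disorder intervals, ontology edge list, disease annotations, long-format
# temporal matrices, Newick sample trees, and gene-label files.

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

write_tsv <- function(df, path, row_names = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
  invisible(path)
}

#' Read/write a gene-label TSV (gene_id, group)
#' @param path file path.
#' @return data.frame with gene_id, group.
#' @export
read_labels <- function(path) {
  df <- read_tsv(path)
  check_that(all(c("gene_id", "group") %in% names(df)),
             "labels file needs gene_id and group columns")
  df
}

#' @rdname read_labels
#' @param labels data.frame with gene_id, group.
#' @export
write_labels <- function(labels, path) write_tsv(labels, path)

#' Read/write an annotation table in flat BioMart-style TSV
#'
#' One row per exon with gene, transcript and exon fields side by side.
#'
#' @param path file path.
#' @return an [annotation_table].
#' @export
read_annotation_tsv <- function(path) {
  df <- read_tsv(path)
  need <- c("gene_id", "chromosome", "gene_start", "gene_end", "strand",
            "transcript_id", "is_canonical", "exon_start", "exon_end",
            "exon_rank")
  check_that(all(need %in% names(df)),
             paste("annotation TSV needs columns:",
                   paste(setdiff(need, names(df)), collapse = ", ")))
  gcols <- c("gene_id", "chromosome", "gene_start", "gene_end", "strand")
  if ("group" %in% names(df)) gcols <- c(gcols, "group")
  genes <- unique(df[gcols])
  names(genes)[names(genes) == "gene_start"] <- "start"
  names(genes)[names(genes) == "gene_end"] <- "end"
  transcripts <- unique(df[c("transcript_id", "gene_id", "is_canonical")])
  names(transcripts)[3] <- "canonical"
  transcripts$canonical <- as.logical(transcripts$canonical)
  exons <- df[c("transcript_id", "exon_start", "exon_end", "exon_rank")]
  names(exons) <- c("transcript_id", "start", "end", "rank")
  annotation_table(genes, transcripts, exons)
}

#' @rdname read_annotation_tsv
#' @param annotation an [annotation_table].
#' @export
write_annotation_tsv <- function(annotation, path) {
  ex <- annotation$exons
  tx <- annotation$transcripts[match(ex$transcript_id,
                                     annotation$transcripts$transcript_id), ]
  gn <- annotation$genes[match(tx$gene_id, annotation$genes$gene_id), ]
  df <- data.frame(gene_id = gn$gene_id, group = gn$group,
                   chromosome = gn$chromosome, gene_start = gn$start,
                   gene_end = gn$end, strand = gn$strand,
                   transcript_id = tx$transcript_id,
                   is_canonical = tx$canonical,
                   exon_start = ex$start, exon_end = ex$end,
                   exon_rank = ex$rank, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read/write an annotation table as GTF
#'
#' 1-based inclusive coordinates; canonical transcripts carry the tag
#' `Ensembl_canonical`. Requires the rtracklayer package.
#'
#' @param path GTF file path.
#' @return an [annotation_table].
#' @export
read_annotation_gtf <- function(path) {
  check_that(requireNamespace("rtracklayer", quietly = TRUE),
             "rtracklayer is required for GTF input")
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  g <- df[df$type == "gene", ]
  genes <- data.frame(gene_id = g$gene_id, chromosome = as.character(g$seqnames),
                      start = g$start, end = g$end,
                      strand = as.character(g$strand),
                      stringsAsFactors = FALSE)
  if ("group" %in% names(g)) genes$group <- g$group
  t <- df[df$type == "transcript", ]
  transcripts <- data.frame(transcript_id = t$transcript_id,
                            gene_id = t$gene_id,
                            canonical = !is.na(t$tag) &
                              t$tag == "Ensembl_canonical",
                            stringsAsFactors = FALSE)
  e <- df[df$type == "exon", ]
  exons <- data.frame(transcript_id = e$transcript_id, start = e$start,
                      end = e$end, rank = as.integer(e$exon_number),
                      stringsAsFactors = FALSE)
  annotation_table(genes, transcripts, exons)
}

#' @rdname read_annotation_gtf
#' @param annotation an [annotation_table].
#' @export
write_annotation_gtf <- function(annotation, path) {
  esc <- function(x) gsub('"', "", x)
  attr_str <- function(...) {
    kv <- list(...)
    paste(vapply(names(kv), function(k)
      sprintf('%s "%s";', k, esc(kv[[k]])), character(1)), collapse = " ")
  }
  lines <- character(0)
  gn <- annotation$genes
  for (i in seq_len(nrow(gn))) {
    lines <- c(lines, paste(gn$chromosome[i], "genediverse", "gene",
                            gn$start[i], gn$end[i], ".", gn$strand[i], ".",
                            attr_str(gene_id = gn$gene_id[i]), sep = "\t"))
    txs <- annotation$transcripts[annotation$transcripts$gene_id ==
                                    gn$gene_id[i], ]
    for (j in seq_len(nrow(txs))) {
      ex <- annotation$exons[annotation$exons$transcript_id ==
                               txs$transcript_id[j], ]
      tag <- if (txs$canonical[j])
        attr_str(gene_id = gn$gene_id[i],
                 transcript_id = txs$transcript_id[j],
                 tag = "Ensembl_canonical") else
        attr_str(gene_id = gn$gene_id[i],
                 transcript_id = txs$transcript_id[j])
      lines <- c(lines, paste(gn$chromosome[i], "genediverse", "transcript",
                              min(ex$start), max(ex$end), ".", gn$strand[i],
                              ".", tag, sep = "\t"))
      for (k in seq_len(nrow(ex))) {
        lines <- c(lines, paste(
          gn$chromosome[i], "genediverse", "exon", ex$start[k], ex$end[k],
          ".", gn$strand[i], ".",
          attr_str(gene_id = gn$gene_id[i],
                   transcript_id = txs$transcript_id[j],
                   exon_number = as.character(ex$rank[k])), sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read/write an isoform tensor as matrix + map TSVs
#'
#' @param matrix_path TSV with a transcript_id column then one column per
#'   sample.
#' @param map_path TSV with transcript_id, gene_id.
#' @return an [isoform_tensor].
#' @export
read_isoform_matrix <- function(matrix_path, map_path) {
  m <- read_tsv(matrix_path)
  check_that(names(m)[1] == "transcript_id",
             "matrix TSV must start with a transcript_id column")
  abund <- as.matrix(m[, -1, drop = FALSE])
  rownames(abund) <- m$transcript_id
  isoform_tensor(abund, read_tsv(map_path))
}

#' @rdname read_isoform_matrix
#' @param tensor an [isoform_tensor].
#' @export
write_isoform_matrix <- function(tensor, matrix_path, map_path) {
  df <- data.frame(transcript_id = rownames(tensor$abund),
                   tensor$abund, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, matrix_path)
  write_tsv(tensor$map, map_path)
  invisible(matrix_path)
}

#' Read/write a complex table (complex_id TAB comma-separated members)
#' @param path file path.
#' @return a [complex_table].
#' @export
read_complex_table <- function(path) {
  df <- read_tsv(path)
  check_that(all(c("complex_id", "members") %in% names(df)),
             "complex table needs complex_id and members columns")
  complex_table(stats::setNames(
    strsplit(df$members, ",", fixed = TRUE), df$complex_id))
}

#' @rdname read_complex_table
#' @param table a [complex_table].
#' @export
write_complex_table <- function(table, path) {
  write_tsv(data.frame(
    complex_id = names(table$members),
    members = vapply(table$members, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE), path)
}

#' Read/write a disorder interval table
#' @param path TSV with protein_id, length, start, end.
#' @return data.frame.
#' @export
read_disorder_table <- function(path) {
  df <- read_tsv(path)
  check_that(all(c("protein_id", "length", "start", "end") %in% names(df)),
             "disorder table needs protein_id, length, start, end")
  df
}

#' @rdname read_disorder_table
#' @param table disorder data.frame.
#' @export
write_disorder_table <- function(table, path) {
  write_tsv(table[intersect(c("protein_id", "group", "length", "start", "end"),
                            names(table))], path)
}

#' Read/write an ontology edge list (child, parent)
#' @param path file path.
#' @param root optional designated root term.
#' @return an [ontology_graph].
#' @export
read_ontology_edges <- function(path, root = NULL) {
  ontology_graph(read_tsv(path), root = root)
}

#' @rdname read_ontology_edges
#' @param graph an [ontology_graph].
#' @export
write_ontology_edges <- function(graph, path) write_tsv(graph$edges, path)

#' Read/write disease annotations
#' @param path TSV with gene_id, disease_id, modes, somatic, susceptibility,
#'   terms (modes/terms semicolon-separated).
#' @return data.frame.
#' @export
read_disease_annotations <- function(path) {
  df <- read_tsv(path)
  need <- c("gene_id", "disease_id", "modes", "somatic", "susceptibility",
            "terms")
  check_that(all(need %in% names(df)),
             paste("disease annotations need columns:",
                   paste(setdiff(need, names(df)), collapse = ", ")))
  df$somatic <- as.logical(df$somatic)
  df$susceptibility <- as.logical(df$susceptibility)
  df
}

#' @rdname read_disease_annotations
#' @param annotations data.frame.
#' @export
write_disease_annotations <- function(annotations, path) {
  write_tsv(as.data.frame(annotations), path)
}

#' Read/write long-format temporal expression
#' @param path TSV with subregion, age_pcw, gene, value, units.
#' @return data.frame.
#' @export
read_temporal_long <- function(path) {
  df <- read_tsv(path)
  check_that(all(c("subregion", "age_pcw", "gene", "value") %in% names(df)),
             "temporal file needs subregion, age_pcw, gene, value")
  df
}

#' @rdname read_temporal_long
#' @param samples data.frame.
#' @export
write_temporal_long <- function(samples, path) write_tsv(samples, path)

#' Read/write a sample tree in Newick format (branch lengths required)
#' @param path Newick file path.
#' @return an [ape::phylo].
#' @export
read_sample_tree <- function(path) {
  tree <- ape::read.tree(path)
  check_that(!is.null(tree$edge.length), "sample tree must have branch lengths")
  tree
}

#' @rdname read_sample_tree
#' @param tree an [ape::phylo].
#' @export
write_sample_tree <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}
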