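#' Annotation table container
#'
#' Bundles gene, transcript and exon records (1-based inclusive coordinates,
#' BioMart/GTF convention) and validates the structural invariants: exactly
#' one canonical transcript per gene, exon ranks contiguous from 1 in
#' transcription order, exons within gene bounds and non-overlapping within
#' a transcript.
#'
#' @param genes data.frame with columns gene_id, group, chromosome, start,
#'   end, strand, biotype.
#' @param transcripts data.frame with columns transcript_id, gene_id,
#'   canonical (logical).
#' @param exons data.frame with columns transcript_id, start, end, rank.
#' @return object of class `annotation_table`.
#' @export
annotation_table <- function(genes, transcripts, exons) {
  need <- function(df, cols, nm) {
    check_that(all(cols %in% names(df)),
               sprintf("%s must have columns: %s", nm,
                       paste(setdiff(cols, names(df)), collapse = ", ")))
  }
  need(genes, c("gene_id", "chromosome", "start", "end", "strand"), "genes")
  need(transcripts, c("transcript_id", "gene_id", "canonical"), "transcripts")
  need(exons, c("transcript_id", "start", "end", "rank"), "exons")
  if (is.null(genes$group)) genes$group <- NA_character_
  if (is.null(genes$biotype)) genes$biotype <- "protein_coding"
  check_that(!anyDuplicated(genes$gene_id), "duplicate gene_id in genes")
  check_that(all(genes$start <= genes$end), "gene start must be <= end")
  check_that(all(exons$start <= exons$end), "exon start must be <= end")
  check_that(all(transcripts$gene_id %in% genes$gene_id),
             "transcript with unknown gene_id")
  check_that(all(exons$transcript_id %in% transcripts$transcript_id),
             "exon with unknown transcript_id")
  n_canon <- tapply(transcripts$canonical, transcripts$gene_id, sum)
  check_that(all(n_canon == 1),
             "each gene must have exactly one canonical transcript")
  by_tx <- split(exons$rank, exons$transcript_id)
  ok_rank <- vapply(by_tx, function(r) all(sort(r) == seq_along(r)),
                    logical(1))
  check_that(all(ok_rank), "exon ranks must be contiguous from 1")
  structure(list(genes = genes, transcripts = transcripts, exons = exons),
            class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat(sprintf("annotation_table: %d genes, %d transcripts, %d exons\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons)))
  invisible(x)
}

#' Gene length as genomic span
#'
#' `end - start + 1` on 1-based inclusive coordinates; strand-independent.
#' Span (not mRNA) scale: introns are included.
#'
#' @param start,end integer vectors of gene coordinates.
#' @return integer vector of lengths in nucleotides.
#' @export
#' @examples
#' gene_length(101, 200) # 100
gene_length <- function(start, end) {
  check_that(all(start >= 1) && all(end >= start),
             "require 1 <= start <= end")
  as.integer(end - start + 1)
}

#' Transcript length as the sum of its exon lengths
#'
#' @param exons data.frame of the transcript's exons (start, end); exons of
#'   one transcript must not overlap.
#' @return transcript length in nucleotides.
#' @export
transcript_length <- function(exons) {
  check_that(nrow(exons) >= 1, "transcript must have at least one exon")
  check_that(all(exons$start <= exons$end), "exon start must be <= end")
  o <- order(exons$start)
  s <- exons$start[o]; e <- exons$end[o]
  if (nrow(exons) > 1 && any(s[-1] <= e[-length(e)])) {
    gd_stop("overlapping exons within one transcript", "gd_invalid_input")
  }
  as.integer(sum(e - s + 1))
}

#' Partition a transcript into first, middle and last exon fractions
#'
#' First and last exons are identified by rank in transcription order
#' (strand-aware), all remaining exons are aggregated as "middle".
#' Single-exon transcripts are excluded by the analysis rules and signalled
#' with a classed `gd_excluded_input` condition. For two-exon transcripts
#' the middle fraction is `NA` (absent), not zero.
#'
#' @param exons data.frame with start, end, rank for one transcript.
#' @return list with first_prop, middle_prop, last_prop, exon_count,
#'   transcript_length.
#' @export
#' @examples
#' ex <- data.frame(start = c(1, 201, 501), end = c(100, 400, 600),
#'                  rank = 1:3)
#' exon_partition(ex) # 0.25, 0.5, 0.25
exon_partition <- function(exons) {
  k <- nrow(exons)
  if (k < 2) excluded_input("single-exon transcript: no exon partition")
  check_that(identical(sort(exons$rank), seq_len(k)),
             "ranks must be contiguous from 1")
  lens <- (exons$end - exons$start + 1)[order(exons$rank)]
  total <- sum(lens)
  list(
    first_prop = lens[1] / total,
    middle_prop = if (k >= 3) sum(lens[2:(k - 1)]) / total else NA_real_,
    last_prop = lens[k] / total,
    exon_count = k,
    transcript_length = as.integer(total)
  )
}

#' Fraction of genes whose canonical transcript is single-exon
#'
#' @param annotation an [annotation_table].
#' @param group optional group label; if given, restrict to that group.
#' @return list with k (single-exon count), n (genes considered), fraction.
#' @export
single_exon_fraction <- function(annotation, group = NULL) {
  genes <- annotation$genes
  if (!is.null(group)) {
    genes <- genes[genes$group %in% group, , drop = FALSE]
    check_that(nrow(genes) > 0, sprintf("no genes with group '%s'",
                                        paste(group, collapse = ",")))
  }
  canon <- annotation$transcripts[annotation$transcripts$canonical, ]
  canon <- canon[canon$gene_id %in% genes$gene_id, , drop = FALSE]
  n_ex <- table(annotation$exons$transcript_id)
  counts <- as.integer(n_ex[canon$transcript_id])
  k <- sum(counts == 1L)
  n <- nrow(canon)
  list(k = k, n = n, fraction = k / n)
}

#' Ordinary least squares with optional log10 transforms
#'
#' Shared regression helper for structure/diversity margins (e.g. transcript
#' length against exon count on log-log scale).
#'
#' @param x,y numeric vectors; values entering a log transform must be > 0.
#' @param log_x,log_y apply log10 before fitting.
#' @return list with slope, intercept, r_squared, n.
#' @export
regress_log <- function(x, y, log_x = TRUE, log_y = TRUE) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  check_that(length(x) >= 3, "need at least 3 finite observations")
  if (log_x) {
    check_that(all(x > 0), "x must be positive for log transform")
    x <- log10(x)
  }
  if (log_y) {
    check_that(all(y > 0), "y must be positive for log transform")
    y <- log10(y)
  }
  check_that(stats::var(x) > 0, "zero variance in x")
  fit <- stats::lm(y ~ x)
  # exact fits are legitimate here; silence summary.lm's perfect-fit notice
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       n = length(x))
}

#' Per-gene structural feature table
#'
#' Canonical-transcript features used by the group comparisons: genomic
#' span, transcript length, exon count, exon partition fractions,
#' single-exon flag and annotated isoform count.
#'
#' @param annotation an [annotation_table].
#' @return data.frame, one row per gene.
#' @export
structure_features <- function(annotation) {
  genes <- annotation$genes
  canon <- annotation$transcripts[annotation$transcripts$canonical, ]
  canon <- canon[match(genes$gene_id, canon$gene_id), ]
  ex_by_tx <- split(annotation$exons, annotation$exons$transcript_id)
  n_iso <- table(annotation$transcripts$gene_id)

  rows <- lapply(seq_len(nrow(genes)), function(i) {
    ex <- ex_by_tx[[canon$transcript_id[i]]]
    part <- if (nrow(ex) >= 2) exon_partition(ex) else
      list(first_prop = NA_real_, middle_prop = NA_real_,
           last_prop = NA_real_, exon_count = nrow(ex),
           transcript_length = transcript_length(ex))
    data.frame(
      gene_id = genes$gene_id[i],
      group = genes$group[i],
      gene_length = gene_length(genes$start[i], genes$end[i]),
      transcript_length = part$transcript_length,
      exon_count = part$exon_count,
      first_prop = part$first_prop,
      middle_prop = part$middle_prop,
      last_prop = part$last_prop,
      single_exon = part$exon_count == 1L,
      n_isoforms = as.integer(n_iso[genes$gene_id[i]]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
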