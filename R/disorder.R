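# Intrinsically disordered region (IDR) statistics. Residue coordinates are
# 1-based inclusive (UniProt convention); stored intervals may overlap and
# are merged on demand, with adjacent intervals (end + 1 == next start)
# joined, since curated files may split maximal regions.

#' Merge residue intervals into disjoint sorted intervals
#'
#' @param intervals matrix or data.frame with columns start, end (1-based
#'   inclusive); may overlap or touch.
#' @param length optional protein length for bounds checking.
#' @return data.frame with disjoint, sorted start/end covering the same
#'   residues; adjacent intervals are merged.
#' @export
#' @examples
#' merge_intervals(data.frame(start = c(1, 11), end = c(20, 30)))
merge_intervals <- function(intervals, length = NULL) {
  intervals <- as.data.frame(intervals)
  if (nrow(intervals) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  check_that(all(c("start", "end") %in% names(intervals)),
             "intervals need start and end columns")
  check_that(all(intervals$start >= 1) && all(intervals$start <= intervals$end),
             "require 1 <= start <= end")
  if (!is.null(length)) {
    check_that(all(intervals$end <= length),
               "interval end exceeds protein length")
  }
  o <- order(intervals$start, intervals$end)
  s <- as.integer(intervals$start[o]); e <- as.integer(intervals$end[o])
  ms <- s[1]; me <- e[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me + 1L) { # overlap or adjacency
      me <- max(me, e[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- s[i]; me <- e[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' Fraction of a protein in disordered regions
#'
#' @param length protein length in residues (>= 1).
#' @param intervals disorder intervals (may be empty).
#' @return merged disordered residues / length, in \[0, 1\].
#' @export
disordered_fraction <- function(length, intervals) {
  check_that(length >= 1, "protein length must be >= 1")
  m <- merge_intervals(intervals, length)
  sum(m$end - m$start + 1) / length
}

#' Length of the largest contiguous disordered region
#'
#' @param intervals disorder intervals; must be non-empty (proteins without
#'   any annotated region are excluded from this statistic).
#' @param length optional protein length for bounds checking.
#' @return longest merged interval length in residues.
#' @export
max_disordered_length <- function(intervals, length = NULL) {
  if (is.null(intervals) || nrow(as.data.frame(intervals)) == 0) {
    excluded_input("no disordered intervals: maximum undefined")
  }
  m <- merge_intervals(intervals, length)
  max(m$end - m$start + 1)
}

#' Does the protein have at least one annotated disordered region?
#'
#' @param intervals disorder intervals (possibly empty or NULL).
#' @return logical.
#' @export
has_disorder <- function(intervals) {
  !is.null(intervals) && nrow(as.data.frame(intervals)) > 0
}

#' Per-protein disorder statistics
#'
#' Concatenates all annotation rows of each protein, merges intervals and
#' reports prevalence, fraction and maximum region length.
#'
#' @param table data.frame with protein_id, length, start, end (one interval
#'   per row; start/end NA for proteins without intervals).
#' @return data.frame with protein_id, length, has_disorder,
#'   disordered_fraction, max_disordered_length (NA when no interval).
#' @export
disorder_stats <- function(table) {
  check_that(all(c("protein_id", "length", "start", "end") %in% names(table)),
             "table needs protein_id, length, start, end")
  rows <- lapply(split(table, table$protein_id), function(df) {
    len <- df$length[1]
    iv <- df[!is.na(df$start) & !is.na(df$end), c("start", "end")]
    data.frame(
      protein_id = df$protein_id[1],
      length = len,
      has_disorder = has_disorder(iv),
      disordered_fraction = disordered_fraction(len, iv),
      max_disordered_length = if (nrow(iv) > 0)
        max_disordered_length(iv, len) else NA_integer_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
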