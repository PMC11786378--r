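# Small fixtures built in code.

# tensor from a named list: gene -> isoform x sample abundance matrix
make_tensor <- function(gene_mats, samples) {
  abund <- do.call(rbind, unname(gene_mats))
  tx <- unlist(lapply(names(gene_mats), function(g)
    sprintf("%s.t%d", g, seq_len(nrow(gene_mats[[g]])))))
  rownames(abund) <- tx
  colnames(abund) <- samples
  map <- data.frame(transcript_id = tx,
                    gene_id = rep(names(gene_mats),
                                  vapply(gene_mats, nrow, integer(1))))
  isoform_tensor(abund, map)
}

uniform_weights <- function(samples) stats::setNames(rep(1, length(samples)),
                                                     samples)

# two systems, one mid-level term, one multi-parent leaf
toy_ontology <- function() {
  ontology_graph(data.frame(
    child  = c("sysA", "sysB", "A1", "A1.1", "B1", "XM"),
    parent = c("root", "root", "sysA", "A1", "sysB", "sysA")),
    root = "root")
}

random_intervals <- function(len, n) {
  s <- sample.int(len, n, replace = TRUE)
  e <- pmin(len, s + sample.int(max(3, len %/% 3), n, replace = TRUE) - 1L)
  data.frame(start = s, end = e)
}
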