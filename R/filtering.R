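# Pre-processing filters: multimapped reads and rRNA-derived reads are
# removed before any coverage, metagene or counting step, with a conservation
# report (input = removed_multimapped + removed_rrna + retained).

#' Remove multimapped reads
#'
#' Retains reads with `hit_count == 1`, preserving input order.
#'
#' @param reads Read data.frame.
#' @return list with `reads` (retained) and `removed` (count).
#' @export
filter_multimapped <- function(reads) {
  keep <- reads$hit_count == 1L
  list(reads = reads[keep, , drop = FALSE], removed = sum(!keep))
}

#' Remove reads overlapping rRNA (or other contaminant) features
#'
#' A read is removed iff it overlaps any feature by >= 1 nt on either strand
#' (strand-agnostic: rRNA contamination is discarded regardless of annotated
#' orientation). Overlap respects circular wrap-around.
#'
#' @param reads Read data.frame.
#' @param rrna_features Feature data.frame (e.g. annotation rows of type
#'   rRNA).
#' @param genomes A `genome_set`.
#' @return list with `reads` (retained) and `removed` (count).
#' @export
filter_rrna <- function(reads, rrna_features, genomes) {
  if (nrow(reads) == 0L || nrow(rrna_features) == 0L) {
    return(list(reads = reads, removed = 0L))
  }
  remove <- rep(FALSE, nrow(reads))
  for (i in seq_len(nrow(rrna_features))) {
    ct <- rrna_features$contig[i]
    g <- get_contig(genomes, ct)  # errors on annotation/genome mismatch
    idx <- reads$contig == ct
    if (!any(idx)) next
    remove[idx] <- remove[idx] |
      overlaps_feature(reads$start[idx], reads$end[idx],
                       rrna_features$start[i], rrna_features$end[i], g$length)
  }
  list(reads = reads[!remove, , drop = FALSE], removed = sum(remove))
}

#' Filter a read set: multimappers first, then rRNA overlap
#'
#' @param reads Read data.frame.
#' @param annotation Feature data.frame; rows with `type` in `rrna_types`
#'   define the contaminant set.
#' @param genomes A `genome_set`.
#' @param rrna_types Feature types treated as contaminants (default rRNA
#'   only; add `"tRNA"` to also drop tRNA reads).
#' @return list with `reads` (retained) and `report`, a one-row data.frame
#'   with `input_reads`, `removed_multimapped`, `removed_rrna`, `retained`.
#' @export
filter_reads <- function(reads, annotation, genomes, rrna_types = "rRNA") {
  n0 <- nrow(reads)
  mm <- filter_multimapped(reads)
  feats <- annotation[annotation$type %in% rrna_types, , drop = FALSE]
  rr <- filter_rrna(mm$reads, feats, genomes)
  report <- data.frame(input_reads = n0,
                       removed_multimapped = mm$removed,
                       removed_rrna = rr$removed,
                       retained = nrow(rr$reads))
  stopifnot(report$retained ==
              report$input_reads - report$removed_multimapped - report$removed_rrna)
  list(reads = rr$reads, report = report)
}
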