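# Per-ORF read counting and expression normalisation.
#
# Counting is strand-specific: a read is assigned to an ORF iff it overlaps
# it by >= 1 nt on the same strand; a read overlapping two or more ORFs is
# discarded as ambiguous (featureCounts-like unique assignment), so
# assigned + ambiguous + unassigned always equals the retained read count.
# Translation efficiency (TE) is the ratio of footprint (RIBO) to
# transcriptome (RNA) coverage: mean RPKM across RIBO replicates over mean
# RPKM across RNA replicates, per condition.

#' Count reads per ORF
#'
#' @param reads Filtered read data.frame.
#' @param orfs Feature data.frame (e.g. merged ORFs) with unique `orf_id`.
#' @param genomes A `genome_set`.
#' @return list: `counts` (named integer vector per `orf_id`), `ambiguous`
#'   (reads overlapping >= 2 ORFs), `unassigned` (reads overlapping none).
#' @export
count_reads <- function(reads, orfs, genomes) {
  counts <- stats::setNames(integer(nrow(orfs)), orfs$orf_id)
  n <- nrow(reads)
  if (n == 0L || nrow(orfs) == 0L) {
    return(list(counts = counts, ambiguous = 0L, unassigned = n))
  }
  n_overlap <- integer(n)
  which_orf <- integer(n)
  for (i in seq_len(nrow(orfs))) {
    g <- get_contig(genomes, orfs$contig[i])
    idx <- which(reads$contig == orfs$contig[i] &
                   reads$strand == orfs$strand[i])
    if (!length(idx)) next
    hit <- overlaps_feature(reads$start[idx], reads$end[idx],
                            orfs$start[i], orfs$end[i], g$length)
    hi <- idx[hit]
    n_overlap[hi] <- n_overlap[hi] + 1L
    which_orf[hi] <- i
  }
  uniq <- n_overlap == 1L
  if (any(uniq)) {
    tab <- tabulate(which_orf[uniq], nbins = nrow(orfs))
    counts[] <- tab
  }
  list(counts = counts, ambiguous = sum(n_overlap >= 2L),
       unassigned = sum(n_overlap == 0L))
}

#' Reads per kilobase per million mapped reads
#'
#' `count * 1e9 / (orf_length_nt * library_size)`.
#'
#' @param count Raw count(s).
#' @param orf_length_nt ORF length(s) in nt (stop codon included).
#' @param library_size Retained reads in the library.
#' @return Numeric RPKM value(s).
#' @export
rpkm <- function(count, orf_length_nt, library_size) {
  stopifnot(all(orf_length_nt > 0))
  if (library_size <= 0) stop("empty library: library_size must be positive")
  count * 1e9 / (orf_length_nt * library_size)
}

#' Transcripts per million
#'
#' `rate_i = count_i / length_i; TPM_i = rate_i * 1e6 / sum(rate)`. Columns
#' sum to 1e6 whenever any count is nonzero.
#'
#' @param counts Raw counts.
#' @param lengths Feature lengths in nt.
#' @return Numeric TPM vector (all zero when all counts are zero).
#' @export
tpm <- function(counts, lengths) {
  stopifnot(all(lengths > 0), length(counts) == length(lengths))
  rate <- counts / lengths
  s <- sum(rate)
  if (s == 0) return(rep(0, length(counts)))
  rate * 1e6 / s
}

#' Translation efficiency from replicate RPKM vectors
#'
#' TE = mean(RIBO RPKM) / mean(RNA RPKM); NA when the RNA mean is zero.
#'
#' @param rpkm_ribo,rpkm_rna Per-replicate RPKM values from the same
#'   condition.
#' @return TE (or NA).
#' @export
translation_efficiency <- function(rpkm_ribo, rpkm_rna) {
  if (length(rpkm_ribo) == 0L || length(rpkm_rna) == 0L) {
    stop("sample-sheet error: a condition needs >= 1 RIBO and >= 1 RNA library for TE")
  }
  mr <- mean(rpkm_rna)
  if (mr == 0) return(NA_real_)
  mean(rpkm_ribo) / mr
}

#' Quantify merged ORFs across all libraries of an experiment
#'
#' Builds the raw count matrix plus RPKM and TPM matrices (library sizes =
#' retained reads per library) and the per-condition TE table.
#'
#' @param merged Annotated `merged_orfs` data.frame (needs `length_nt`).
#' @param reads_by_library Named list of filtered read data.frames, keyed by
#'   `library_id`.
#' @param sample_sheet Sample-sheet data.frame.
#' @param genomes A `genome_set`.
#' @return list: `counts`, `rpkm`, `tpm` (matrices, rows = orf_id, cols =
#'   library_id), `library_sizes`, `te` (matrix rows = orf_id, cols =
#'   conditions), `diagnostics` (per-library assigned/ambiguous/unassigned).
#' @export
quantify_orfs <- function(merged, reads_by_library, sample_sheet, genomes) {
  libs <- sample_sheet$library_id
  stopifnot(all(libs %in% names(reads_by_library)))
  orf_ids <- merged$orf_id
  lens <- merged$end - merged$start
  cm <- matrix(0L, nrow = length(orf_ids), ncol = length(libs),
               dimnames = list(orf_ids, libs))
  rk <- tp <- matrix(0, nrow = length(orf_ids), ncol = length(libs),
                     dimnames = list(orf_ids, libs))
  lib_sizes <- stats::setNames(integer(length(libs)), libs)
  diag <- data.frame(library_id = libs, assigned = 0L, ambiguous = 0L,
                     unassigned = 0L, stringsAsFactors = FALSE)
  for (j in seq_along(libs)) {
    reads <- reads_by_library[[libs[j]]]
    lib_sizes[j] <- nrow(reads)
    cr <- count_reads(reads, merged, genomes)
    cm[, j] <- cr$counts
    diag$assigned[j] <- sum(cr$counts)
    diag$ambiguous[j] <- cr$ambiguous
    diag$unassigned[j] <- cr$unassigned
    if (lib_sizes[j] > 0L) {
      rk[, j] <- rpkm(cr$counts, lens, lib_sizes[j])
    }
    tp[, j] <- tpm(cr$counts, lens)
  }
  conditions <- unique(sample_sheet$condition)
  te <- matrix(NA_real_, nrow = length(orf_ids), ncol = length(conditions),
               dimnames = list(orf_ids, conditions))
  for (cond in conditions) {
    ribo_libs <- sample_sheet$library_id[sample_sheet$condition == cond &
                                           sample_sheet$method == "RIBO"]
    rna_libs <- sample_sheet$library_id[sample_sheet$condition == cond &
                                          sample_sheet$method == "RNA"]
    if (length(ribo_libs) == 0L) next
    if (length(rna_libs) == 0L) {
      stop("sample-sheet error: condition '", cond,
           "' has RIBO libraries but no RNA library (TE undefined)")
    }
    for (i in seq_along(orf_ids)) {
      te[i, cond] <- translation_efficiency(rk[i, ribo_libs], rk[i, rna_libs])
    }
  }
  list(counts = cm, rpkm = rk, tpm = tp, library_sizes = lib_sizes, te = te,
       diagnostics = diag)
}
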