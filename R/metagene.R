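# Metagene profiling of ribosome density around annotated start codons.
#
# For every CDS start, reads anchored (by default at their 5' end) within a
# window [-window_upstream, window_downstream - 1] relative to the first
# nucleotide of the start codon are tallied into a read-length x offset count
# matrix. Offset 0 is the A of ATG; offsets increase in the reading
# direction. The per-frame summary then measures three-nucleotide
# periodicity: the fraction of coding-side signal at offsets congruent to
# 0, 1, 2 mod 3, per read length — a data-quality diagnostic and a guide to
# which footprint lengths carry frame information.

#' Collect start-codon positions from an annotation
#'
#' The start position is the first nucleotide of the start codon:
#' `interval.start` on the plus strand, `interval.end - 1` on the minus
#' strand. Genes whose full profiling window would cross the edge of a
#' *linear* contig are excluded (and counted); on circular contigs windows
#' wrap.
#'
#' @param annotation Feature data.frame; rows with `type` in `types` are
#'   used.
#' @param genomes A `genome_set`.
#' @param window_upstream,window_downstream Window extents in nt.
#' @param types Feature types treated as genes (default `"CDS"`).
#' @return list with `starts` (data.frame `contig`, `strand`, `pos`) and
#'   `excluded` (count of edge-excluded genes).
#' @export
collect_start_positions <- function(annotation, genomes,
                                    window_upstream = 50L,
                                    window_downstream = 50L,
                                    types = "CDS") {
  cds <- annotation[annotation$type %in% types, , drop = FALSE]
  n <- nrow(cds)
  keep <- logical(n)
  pos <- integer(n)
  for (i in seq_len(n)) {
    g <- get_contig(genomes, cds$contig[i])
    if (cds$strand[i] == "+") {
      p <- cds$start[i]
      ok <- g$circular ||
        (p - window_upstream >= 0L && p + window_downstream <= g$length)
    } else {
      p <- cds$end[i] - 1L
      ok <- g$circular ||
        (p + window_upstream <= g$length - 1L && p - window_downstream + 1L >= 0L)
    }
    pos[i] <- if (g$circular) p %% g$length else p
    keep[i] <- ok
  }
  list(starts = data.frame(contig = cds$contig[keep], strand = cds$strand[keep],
                           pos = pos[keep], stringsAsFactors = FALSE),
       excluded = sum(!keep))
}

#' Metagene profile around start codons
#'
#' For each read whose length lies in `read_lengths` and whose anchor lands
#' in some gene's window on the matching strand, the (read length, offset)
#' cell is incremented; offset = anchor - start on the plus strand and
#' start - anchor on the minus strand, with circular wrap. A read landing in
#' k overlapping windows contributes k increments.
#'
#' @param reads Filtered read data.frame.
#' @param starts Start-position data.frame from [collect_start_positions()].
#' @param genomes A `genome_set`.
#' @param window_upstream,window_downstream Window extents in nt (defaults
#'   50/50, bracketing bacterial ribosome footprints).
#' @param read_lengths Integer vector of read lengths kept (default 20:45).
#' @param anchor Anchor mode: `"fiveprime"` (default), `"threeprime"`,
#'   `"center"`.
#' @return Object of class `metagene_profile`: `counts` matrix (rows = read
#'   lengths, columns = offsets `-window_upstream .. window_downstream - 1`),
#'   `window_upstream`, `window_downstream`, `read_lengths`, `anchor`,
#'   `n_genes`.
#' @export
metagene_profile <- function(reads, starts, genomes,
                             window_upstream = 50L, window_downstream = 50L,
                             read_lengths = 20:45, anchor = "fiveprime") {
  anchor <- match.arg(anchor, c("fiveprime", "threeprime", "center"))
  offsets <- seq.int(-window_upstream, window_downstream - 1L)
  counts <- matrix(0L, nrow = length(read_lengths), ncol = length(offsets),
                   dimnames = list(as.character(read_lengths),
                                   as.character(offsets)))
  r <- reads[reads$read_length %in% read_lengths, , drop = FALSE]
  if (nrow(r) > 0L && nrow(starts) > 0L) {
    # anchors per contig (wrap depends on contig length)
    anc <- integer(nrow(r))
    for (ct in unique(r$contig)) {
      idx <- r$contig == ct
      anc[idx] <- anchor_position(r[idx, , drop = FALSE], anchor,
                                  get_contig(genomes, ct))
    }
    for (i in seq_len(nrow(starts))) {
      g <- get_contig(genomes, starts$contig[i])
      idx <- which(r$contig == starts$contig[i] & r$strand == starts$strand[i])
      if (!length(idx)) next
      d_raw <- if (starts$strand[i] == "+") anc[idx] - starts$pos[i]
               else starts$pos[i] - anc[idx]
      if (g$circular) {
        d <- ((d_raw + window_upstream) %% g$length) - window_upstream
      } else {
        d <- d_raw
      }
      inw <- d >= -window_upstream & d <= window_downstream - 1L
      if (!any(inw)) next
      li <- match(as.character(r$read_length[idx][inw]), rownames(counts))
      oi <- match(as.character(d[inw]), colnames(counts))
      for (k in seq_along(li)) counts[li[k], oi[k]] <- counts[li[k], oi[k]] + 1L
    }
  }
  structure(list(counts = counts, window_upstream = window_upstream,
                 window_downstream = window_downstream,
                 read_lengths = read_lengths, anchor = anchor,
                 n_genes = nrow(starts)),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("<metagene_profile> %d genes, window -%d..+%d, anchor=%s, total signal %d\n",
              x$n_genes, x$window_upstream, x$window_downstream - 1L,
              x$anchor, sum(x$counts)))
  invisible(x)
}

#' Per-read-length reading-frame summary
#'
#' Sums the profile over coding-side offsets (0 .. window_downstream - 1)
#' grouped by offset mod 3 and normalises per read length. Rows with no
#' signal get all-zero fractions.
#'
#' @param profile A `metagene_profile`.
#' @return Matrix with rows = read lengths and columns `frame0`, `frame1`,
#'   `frame2`; each row sums to 1 (or 0 without signal).
#' @export
frame_summary <- function(profile) {
  offs <- as.integer(colnames(profile$counts))
  coding <- offs >= 0L
  fr <- offs[coding] %% 3L
  out <- t(apply(profile$counts[, coding, drop = FALSE], 1L, function(row) {
    s <- vapply(0:2, function(f) sum(row[fr == f]), numeric(1))
    tot <- sum(s)
    if (tot > 0) s / tot else c(0, 0, 0)
  }))
  colnames(out) <- c("frame0", "frame1", "frame2")
  out
}

#' Write a metagene profile (and optionally its row-normalised variant)
#'
#' TSV with read lengths as rows and offsets as columns. The normalised
#' variant scales each read-length row to sum 1, for cross-length comparison.
#'
#' @param profile A `metagene_profile`.
#' @param path Output TSV.
#' @param normalized Also write `<path base>.normalized.tsv`?
#' @export
write_metagene <- function(profile, path, normalized = TRUE) {
  df <- data.frame(read_length = rownames(profile$counts), profile$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (normalized) {
    rs <- rowSums(profile$counts)
    norm <- profile$counts / ifelse(rs > 0, rs, 1)
    dfn <- data.frame(read_length = rownames(norm), signif(norm, 6),
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(dfn, sub("\\.tsv$", ".normalized.tsv", path),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write a frame summary table
#'
#' @param fs Matrix from [frame_summary()].
#' @param path Output TSV.
#' @export
write_frame_summary <- function(fs, path) {
  df <- data.frame(read_length = rownames(fs), signif(fs, 6),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
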