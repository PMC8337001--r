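# Coordinate conventions
#
# All internal coordinates are 0-based, half-open [start, end). GFF3 I/O is
# 1-based inclusive and wiggle output 1-based; conversions happen only at the
# I/O boundary. On circular contigs an origin-spanning feature is stored
# "unwrapped": start in [0, length) and end > length, so that end - start is
# always the feature length. Negative or wrapped coordinates never appear in
# the internal representation.

#' Construct a genome sequence
#'
#' A single contig: an identifier, its nucleotide sequence and a circularity
#' flag. Bacterial chromosomes and most plasmids are circular; setting
#' `circular = TRUE` enables modular coordinate arithmetic so that features
#' and reads may span the origin.
#'
#' @param contig_id Non-empty contig identifier.
#' @param sequence Nucleotide string over A, C, G, T, N (case-insensitive;
#'   stored upper-case).
#' @param circular Logical; is the contig circular?
#' @return An object of class `genome_sequence` with fields `contig_id`,
#'   `sequence`, `length` and `circular`.
#' @export
genome_sequence <- function(contig_id, sequence, circular = FALSE) {
  stopifnot(is.character(contig_id), length(contig_id) == 1L, nzchar(contig_id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence for contig '", contig_id,
         "' contains characters outside {A,C,G,T,N}")
  }
  structure(
    list(contig_id = contig_id, sequence = sequence,
         length = nchar(sequence), circular = isTRUE(circular)),
    class = "genome_sequence"
  )
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("<genome_sequence> %s: %d nt, %s\n", x$contig_id, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Bundle genome sequences into a genome set
#'
#' @param ... `genome_sequence` objects.
#' @return Named list of class `genome_set`, keyed by contig id.
#' @export
genome_set <- function(...) {
  gs <- list(...)
  if (length(gs) == 1L && is.list(gs[[1L]]) &&
      !inherits(gs[[1L]], "genome_sequence")) {
    gs <- gs[[1L]]
  }
  ok <- vapply(gs, inherits, logical(1), "genome_sequence")
  if (!all(ok)) stop("genome_set() expects genome_sequence objects")
  ids <- vapply(gs, `[[`, character(1), "contig_id")
  if (anyDuplicated(ids)) stop("duplicate contig ids in genome set: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(gs) <- ids
  class(gs) <- "genome_set"
  gs
}

#' Look up a contig in a genome set
#'
#' @param genomes A `genome_set` or a single `genome_sequence`.
#' @param contig_id Contig identifier.
#' @return The `genome_sequence` for that contig.
#' @export
get_contig <- function(genomes, contig_id) {
  if (inherits(genomes, "genome_sequence")) {
    if (genomes$contig_id != contig_id) {
      stop("unknown contig '", contig_id, "'")
    }
    return(genomes)
  }
  g <- genomes[[contig_id]]
  if (is.null(g)) stop("unknown contig '", contig_id, "'")
  g
}

stop_coord <- function(...) {
  stop(errorCondition(paste0(...), class = c("riboloop_coordinate_error",
                                             "error", "condition")))
}

#' Normalize a genomic position onto a contig
#'
#' On a circular contig any integer position (negative, or beyond the contig
#' end) is mapped into `[0, length)` by modular arithmetic; ORFs that span the
#' origin are sometimes reported by external tools with negative coordinates,
#' and this is the canonical fix. On a linear contig only in-range positions
#' are valid.
#'
#' @param pos Integer position(s), 0-based.
#' @param genome A `genome_sequence`.
#' @return Position(s) in `[0, length)`.
#' @export
normalize_coordinate <- function(pos, genome) {
  if (genome$circular) return(pos %% genome$length)
  bad <- pos < 0 | pos >= genome$length
  if (any(bad)) {
    stop_coord("position ", pos[bad][1L], " out of range on linear contig '",
               genome$contig_id, "' (length ", genome$length, ")")
  }
  pos
}

#' Canonicalize possibly wrapped or negative interval coordinates
#'
#' Converts an externally supplied (start, end) pair — which for an
#' origin-spanning feature on a circular contig may satisfy `end < start`
#' (wrapped 1-based GFF3 style, already shifted to 0-based half-open) or use
#' negative positions — into the internal unwrapped representation with
#' `start` in `[0, length)` and `end > start`, where `end > length` exactly
#' when the feature spans the origin.
#'
#' @param start,end 0-based half-open coordinates as given.
#' @param strand `"+"` or `"-"`.
#' @param genome A `genome_sequence`.
#' @return A one-row data.frame with columns `contig`, `start`, `end`,
#'   `strand`.
#' @export
unwrap_interval <- function(start, end, strand, genome) {
  stopifnot(strand %in% c("+", "-"))
  len <- genome$length
  if (!genome$circular) {
    if (end <= start) {
      stop_coord("malformed annotation on linear contig '", genome$contig_id,
                 "': end (", end, ") <= start (", start, ")")
    }
    if (start < 0 || end > len) {
      stop_coord("interval [", start, ",", end, ") exceeds linear contig '",
                 genome$contig_id, "' (length ", len, ")")
    }
    return(data.frame(contig = genome$contig_id, start = start, end = end,
                      strand = strand, stringsAsFactors = FALSE))
  }
  width <- if (end > start) end - start else (end - start) %% len
  if (width <= 0L || width > len) {
    stop_coord("cannot unwrap interval (", start, ",", end, ") on circular contig '",
               genome$contig_id, "' (length ", len, ")")
  }
  s <- start %% len
  data.frame(contig = genome$contig_id, start = s, end = s + width,
             strand = strand, stringsAsFactors = FALSE)
}

#' Enumerate the wrapped genomic positions covered by an interval
#'
#' @param start,end Internal 0-based half-open coordinates (`end` may exceed
#'   the contig length on circular contigs).
#' @param genome A `genome_sequence`.
#' @return Integer vector of positions in `[0, length)`, in 5'->3' order on
#'   the forward strand.
#' @export
interval_positions <- function(start, end, genome) {
  if (end <= start) stop_coord("empty interval [", start, ",", end, ")")
  if (!genome$circular && end > genome$length) {
    stop_coord("interval [", start, ",", end, ") exceeds linear contig '",
               genome$contig_id, "'")
  }
  seq.int(start, end - 1L) %% genome$length
}

# reverse complement of a nucleotide string (vectorised)
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, NULL, fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Extract the nucleotide sequence of a genomic interval
#'
#' Returns the forward-strand substring, wrapping across the origin on
#' circular contigs when `end > length`, reverse-complemented when
#' `strand == "-"`. The result length always equals `end - start`.
#'
#' @param contig Contig id (looked up in `genomes`).
#' @param start,end Internal 0-based half-open coordinates.
#' @param strand `"+"` or `"-"`.
#' @param genomes A `genome_set` or `genome_sequence`.
#' @return Nucleotide string of length `end - start`.
#' @export
extract_sequence <- function(contig, start, end, strand, genomes) {
  g <- get_contig(genomes, contig)
  len <- g$length
  if (end <= start) stop_coord("empty interval [", start, ",", end, ")")
  if (end > len) {
    if (!g$circular) {
      stop_coord("interval [", start, ",", end, ") exceeds linear contig '",
                 contig, "' (length ", len, ")")
    }
    if (end - start > len) {
      stop_coord("interval longer than circular contig '", contig, "'")
    }
    fwd <- paste0(substr(g$sequence, start + 1L, len),
                  substr(g$sequence, 1L, end - len))
  } else {
    if (start < 0) stop_coord("negative start ", start, "; unwrap first")
    fwd <- substr(g$sequence, start + 1L, end)
  }
  if (strand == "-") revcomp(fwd) else fwd
}

# Split an (unwrapped) interval into at most two linear segments on [0, len).
# Returns a list of c(start, end) pairs. Used by overlap tests and coverage.
wrap_segments <- function(start, end, len) {
  if (end <= len) {
    list(c(start, end))
  } else {
    list(c(start, len), c(0L, end - len))
  }
}

# Vectorised strandless overlap test of reads (s1, e1 vectors, unwrapped)
# against a single feature interval (s2, e2, unwrapped) on a contig of given
# length. Any shared wrapped position counts.
overlaps_feature <- function(s1, e1, s2, e2, len) {
  a1s <- s1; a1e <- pmin(e1, len)
  a2s <- rep.int(0L, length(s1)); a2e <- pmax(e1 - len, 0L)
  fs <- wrap_segments(s2, e2, len)
  hit <- rep(FALSE, length(s1))
  for (seg in fs) {
    hit <- hit |
      (a1s < seg[2L] & seg[1L] < a1e) |
      (a2s < seg[2L] & seg[1L] < a2e & a2e > 0L)
  }
  hit
}
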