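# Per-nucleotide coverage tracks.
#
# Four mapping modes: `full` increments every position a read covers;
# `fiveprime` / `threeprime` / `center` increment a single anchor nucleotide
# per read (single-nucleotide mapping). In the single-nucleotide modes a raw
# track's total equals the number of contributing reads exactly — the
# conservation property the tests lean on. Tracks are strand-specific and
# wrap across the origin on circular contigs.

#' Anchor position of a read under a single-nucleotide mapping mode
#'
#' The biological 5' end of a reverse-strand read is its maximum coordinate
#' (`end - 1`), the 3' end its `start`. The center of an even-length read is
#' the left of the two central nucleotides. Results are wrapped into
#' `[0, length)` on circular contigs.
#'
#' @param reads Read data.frame.
#' @param mode One of `"fiveprime"`, `"threeprime"`, `"center"`.
#' @param genome `genome_sequence` the reads lie on.
#' @return Integer vector of genomic positions.
#' @export
anchor_position <- function(reads, mode, genome) {
  mode <- match.arg(mode, c("fiveprime", "threeprime", "center"))
  plus <- reads$strand == "+"
  off <- (reads$read_length - 1L) %/% 2L
  anchor <- switch(mode,
    fiveprime  = ifelse(plus, reads$start, reads$end - 1L),
    threeprime = ifelse(plus, reads$end - 1L, reads$start),
    center     = ifelse(plus, reads$start + off, reads$end - 1L - off)
  )
  normalize_coordinate(anchor, genome)
}

#' Compute a strand-specific coverage track
#'
#' @param reads Filtered read data.frame (any contigs/strands; the subset on
#'   `genome`'s contig and `strand` contributes).
#' @param genome A `genome_sequence`.
#' @param mode `"full"`, `"fiveprime"`, `"threeprime"` or `"center"`.
#' @param strand `"+"` or `"-"`.
#' @return Object of class `coverage_track`: list with `contig_id`, `strand`,
#'   `mode`, `normalization` (`"raw"`), and `values` (length = contig length).
#' @export
compute_coverage <- function(reads, genome, mode, strand) {
  mode <- match.arg(mode, c("full", "fiveprime", "threeprime", "center"))
  stopifnot(strand %in% c("+", "-"))
  len <- genome$length
  idx <- reads$contig == genome$contig_id & reads$strand == strand
  r <- reads[idx, , drop = FALSE]
  values <- numeric(len)
  if (nrow(r) > 0L) {
    if (!genome$circular && any(r$end > len)) {
      stop_coord("read exceeds linear contig '", genome$contig_id, "'")
    }
    if (mode == "full") {
      # difference-array accumulation; origin-spanning reads split in two
      delta <- numeric(len + 1L)
      s1 <- r$start; e1 <- pmin(r$end, len)
      t1 <- tabulate(s1 + 1L, nbins = len)
      delta[seq_len(len)] <- delta[seq_len(len)] + t1
      te <- tabulate(e1 + 1L, nbins = len + 1L)
      delta <- delta - te
      wrap <- r$end > len
      if (any(wrap)) {
        e2 <- r$end[wrap] - len
        delta[1L] <- delta[1L] + sum(wrap)
        t2 <- tabulate(e2 + 1L, nbins = len + 1L)
        delta <- delta - t2
      }
      values <- cumsum(delta[seq_len(len)])
    } else {
      a <- anchor_position(r, mode, genome)
      values <- as.numeric(tabulate(a + 1L, nbins = len))
    }
  }
  structure(list(contig_id = genome$contig_id, strand = strand, mode = mode,
                 normalization = "raw", values = values),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s (%s) mode=%s norm=%s length=%d sum=%g\n",
              x$contig_id, x$strand, x$mode, x$normalization,
              length(x$values), sum(x$values)))
  invisible(x)
}

#' Scale a raw track to counts per million
#'
#' @param track A `coverage_track` with raw values.
#' @param library_size Number of retained reads in the library (both strands,
#'   all contigs, after filtering).
#' @return The track with values scaled by `1e6 / library_size` and
#'   `normalization = "cpm"`.
#' @export
normalize_cpm <- function(track, library_size) {
  if (library_size <= 0) stop("empty library: library_size must be positive")
  track$values <- track$values * 1e6 / library_size
  track$normalization <- "cpm"
  track
}

format_track_value <- function(v) {
  ifelse(v == round(v), format(v, scientific = FALSE, trim = TRUE),
         sprintf("%.10g", v))
}

#' Write a coverage track as wiggle (variableStep, 1-based)
#'
#' Only nonzero positions are written.
#'
#' @param track A `coverage_track`.
#' @param path Output file.
#' @export
write_wiggle <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=wiggle_0 name=\"%s_%s_%s_%s\"",
                     track$contig_id, track$strand, track$mode,
                     track$normalization), con)
  writeLines(sprintf("variableStep chrom=%s", track$contig_id), con)
  nz <- which(track$values != 0)
  if (length(nz)) {
    writeLines(paste(nz, format_track_value(track$values[nz])), con)
  }
  invisible(path)
}

#' Read a wiggle file back into a values vector
#'
#' Supports the variableStep single-contig files written by [write_wiggle()].
#'
#' @param path Wiggle file.
#' @param genome `genome_sequence` giving the contig length.
#' @return Numeric vector of per-position values.
#' @export
read_wiggle <- function(path, genome) {
  lines <- readLines(path)
  dat <- lines[!grepl("^(track|variableStep|fixedStep|#)", lines) & nzchar(lines)]
  values <- numeric(genome$length)
  if (length(dat)) {
    sp <- strsplit(dat, "[ \t]+")
    pos <- vapply(sp, function(x) as.integer(x[1L]), integer(1))
    val <- vapply(sp, function(x) as.numeric(x[2L]), numeric(1))
    values[pos] <- val
  }
  values
}

#' Write a coverage track as bedGraph (0-based half-open, run-length
#' collapsed; zero runs omitted)
#'
#' @param track A `coverage_track`.
#' @param path Output file.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s_%s_%s_%s\"",
                     track$contig_id, track$strand, track$mode,
                     track$normalization), con)
  r <- rle(track$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  nz <- r$values != 0
  if (any(nz)) {
    writeLines(paste(track$contig_id, starts[nz], ends[nz],
                     format_track_value(r$values[nz]), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a bedGraph file back into a values vector
#'
#' @param path bedGraph file.
#' @param genome `genome_sequence` giving the contig length.
#' @return Numeric vector of per-position values.
#' @export
read_bedgraph <- function(path, genome) {
  lines <- readLines(path)
  dat <- lines[!grepl("^(track|#)", lines) & nzchar(lines)]
  values <- numeric(genome$length)
  for (ln in dat) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    values[(as.integer(f[2L]) + 1L):as.integer(f[3L])] <- as.numeric(f[4L])
  }
  values
}

#' Compute and write all coverage tracks for one library
#'
#' One file per (contig, strand, mode, normalization), named
#' `<library>.<contig>.<mode>.<norm>[.rev].wig/.bedgraph` — minus-strand
#' values are non-negative in separate `.rev` files.
#'
#' @param reads Filtered read data.frame.
#' @param genomes A `genome_set`.
#' @param out_dir Output directory (created).
#' @param library_id Label used in file names.
#' @param modes Subset of `c("full","fiveprime","threeprime","center")`.
#' @param normalizations Subset of `c("raw","cpm")`.
#' @return Character vector of files written, invisibly.
#' @export
write_coverage_tracks <- function(reads, genomes, out_dir, library_id,
                                  modes = c("full", "fiveprime", "threeprime",
                                            "center"),
                                  normalizations = c("raw", "cpm")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  library_size <- nrow(reads)
  files <- character(0)
  for (g in genomes) {
    for (strand in c("+", "-")) {
      sfx <- if (strand == "-") ".rev" else ""
      for (mode in modes) {
        raw <- compute_coverage(reads, g, mode, strand)
        for (norm in normalizations) {
          tr <- if (norm == "cpm") normalize_cpm(raw, library_size) else raw
          base <- file.path(out_dir, sprintf("%s.%s.%s.%s%s", library_id,
                                             g$contig_id, mode, norm, sfx))
          write_wiggle(tr, paste0(base, ".wig"))
          write_bedgraph(tr, paste0(base, ".bedgraph"))
          files <- c(files, paste0(base, ".wig"), paste0(base, ".bedgraph"))
        }
      }
    }
  }
  invisible(files)
}
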