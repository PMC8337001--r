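# Standard-format readers and writers.
#
# GFF3 is 1-based inclusive; internal coordinates are 0-based half-open
# (start_internal = start_gff - 1, end_internal = end_gff). Origin-spanning
# features on circular contigs are written as a single record with *wrapped*
# 1-based coordinates (end_gff < start_gff) plus an `origin_spanning=true`
# attribute, and are re-unwrapped on reading. This wrapped-record convention
# is why the GFF3 code here is bespoke: range containers that require
# end >= start cannot carry such records.

#' Read a FASTA file into a genome set
#'
#' Circularity is not part of FASTA; it is taken from a `circular=true` token
#' in the header description (as written by [simulate_dataset()]) or from the
#' `circular` argument, which overrides the header.
#'
#' @param path FASTA file.
#' @param circular `NULL` (use header token, default linear), a single
#'   logical applied to all contigs, or a named logical vector by contig id.
#' @return A `genome_set`.
#' @export
read_fasta <- function(path, circular = NULL) {
  dss <- Biostrings::readDNAStringSet(path)
  headers <- names(dss)
  ids <- sub("\\s.*$", "", headers)
  circ_hdr <- grepl("circular=true", headers, fixed = TRUE)
  gs <- lapply(seq_along(dss), function(i) {
    circ <- circ_hdr[i]
    if (!is.null(circular)) {
      circ <- if (length(circular) == 1L && is.null(names(circular))) {
        isTRUE(circular)
      } else {
        isTRUE(circular[[ids[i]]])
      }
    }
    genome_sequence(ids[i], as.character(dss[[i]]), circular = circ)
  })
  genome_set(gs)
}

#' Write a genome set to FASTA
#'
#' Circular contigs carry a `circular=true` header token so that
#' [read_fasta()] restores the flag.
#'
#' @param genomes A `genome_set`.
#' @param path Output file.
#' @export
write_fasta <- function(genomes, path) {
  seqs <- Biostrings::DNAStringSet(vapply(genomes, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(genomes, function(g) {
    if (g$circular) paste0(g$contig_id, " circular=true") else g$contig_id
  }, character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Parse one attribute out of a GFF3 column-9 string
#'
#' @param attrs Character vector of `key=value;...` strings.
#' @param key Attribute key.
#' @return Character vector (NA where absent).
#' @export
gff_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0("(?:^|;)\\s*", key, "=([^;]*)"), attrs))
  vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_,
         character(1))
}

#' Read a GFF3 annotation or prediction file
#'
#' Coordinates are converted to the internal 0-based half-open convention.
#' Records whose 1-based end is smaller than their start are treated as
#' wrapped origin-spanning features on circular contigs and unwrapped; on a
#' linear contig they raise a parse error. When `genomes` is supplied every
#' record's contig must be known.
#'
#' @param path GFF3 file.
#' @param genomes Optional `genome_set` used for contig validation and
#'   unwrapping (required if the file contains wrapped records).
#' @return A data.frame of features: `orf_id`, `contig`, `start`, `end`,
#'   `strand`, `type`, `source`, `score`, `attributes` (raw column 9).
#' @export
read_gff3 <- function(path, genomes = NULL) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(orf_id = character(), contig = character(),
                      start = integer(), end = integer(), strand = character(),
                      type = character(), source = character(),
                      score = numeric(), attributes = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol_ok <- lengths(parts) == 9L
  if (!all(ncol_ok)) {
    stop("malformed GFF3 record at line ", lineno[which(!ncol_ok)[1L]],
         " of '", path, "': expected 9 tab-separated columns, got ",
         lengths(parts)[which(!ncol_ok)[1L]])
  }
  m <- do.call(rbind, parts)
  contig <- m[, 1L]
  start_gff <- suppressWarnings(as.integer(m[, 4L]))
  end_gff <- suppressWarnings(as.integer(m[, 5L]))
  if (anyNA(start_gff) || anyNA(end_gff)) {
    bad <- which(is.na(start_gff) | is.na(end_gff))[1L]
    stop("non-numeric coordinates at line ", lineno[bad], " of '", path, "'")
  }
  strand <- m[, 7L]
  n <- length(contig)
  start <- integer(n); end <- integer(n)
  for (i in seq_len(n)) {
    if (!is.null(genomes)) {
      g <- tryCatch(get_contig(genomes, contig[i]), error = function(e) {
        stop("unknown contig '", contig[i], "' at line ", lineno[i],
             " of '", path, "'", call. = FALSE)
      })
    } else g <- NULL
    if (end_gff[i] >= start_gff[i]) {
      start[i] <- start_gff[i] - 1L
      end[i] <- end_gff[i]
      if (!is.null(g) && (!g$circular) && end[i] > g$length) {
        stop("feature exceeds linear contig '", contig[i], "' at line ",
             lineno[i], " of '", path, "'")
      }
    } else {
      # wrapped origin-spanning record
      if (is.null(g)) {
        stop("wrapped record (end < start) at line ", lineno[i], " of '",
             path, "' requires a genome set for unwrapping")
      }
      if (!g$circular) {
        stop("malformed annotation at line ", lineno[i], " of '", path,
             "': end < start on linear contig '", contig[i], "'")
      }
      iv <- unwrap_interval(start_gff[i] - 1L, end_gff[i], strand[i], g)
      start[i] <- iv$start
      end[i] <- iv$end
    }
  }
  attrs <- m[, 9L]
  ids <- gff_attr(attrs, "ID")
  ids[is.na(ids)] <- paste0("feature_", seq_len(n))[is.na(ids)]
  data.frame(orf_id = ids, contig = contig, start = start, end = end,
             strand = strand, type = m[, 3L], source = m[, 2L],
             score = suppressWarnings(as.numeric(m[, 6L])),
             attributes = attrs, stringsAsFactors = FALSE)
}

#' Write features to GFF3
#'
#' Origin-spanning features (internal `end` > contig length) are emitted as a
#' single record with wrapped 1-based coordinates (`end_gff < start_gff`) and
#' an `origin_spanning=true` attribute.
#'
#' @param orfs Feature data.frame as returned by [read_gff3()].
#' @param path Output file.
#' @param genomes A `genome_set` (needed to wrap origin-spanning features).
#' @export
write_gff3 <- function(orfs, path, genomes = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(orfs) == 0L) return(invisible(path))
  for (i in seq_len(nrow(orfs))) {
    len <- if (!is.null(genomes)) get_contig(genomes, orfs$contig[i])$length else NA
    s <- orfs$start[i]; e <- orfs$end[i]
    attrs <- orfs$attributes[i]
    if (is.na(attrs) || !nzchar(attrs)) attrs <- paste0("ID=", orfs$orf_id[i])
    if (!is.na(len) && e > len) {
      start_gff <- s + 1L
      end_gff <- e - len
      if (!grepl("origin_spanning=", attrs)) {
        attrs <- paste0(attrs, ";origin_spanning=true")
      }
    } else {
      start_gff <- s + 1L
      end_gff <- e
    }
    score <- orfs$score[i]
    writeLines(paste(orfs$contig[i],
                     if (is.na(orfs$source[i])) "." else orfs$source[i],
                     orfs$type[i], start_gff, end_gff,
                     if (is.na(score)) "." else format(score, trim = TRUE),
                     orfs$strand[i], ".", attrs, sep = "\t"), con)
  }
  invisible(path)
}

# reference span consumed by a CIGAR string (M, D, N, =, X ops)
cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1L]]
    n <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Read mapped reads from a SAM (or BAM) file
#'
#' Each mapped record becomes one ungapped read block covering its reference
#' span; reads whose CIGAR contains indels use the reference span, with one
#' warning per file. Multimapping status comes from the `NH` tag when present,
#' otherwise from a `MAPQ == 0` heuristic (warned once). On circular contigs
#' an alignment may run past the contig end (origin-spanning, unwrapped
#' `end > length`); on linear contigs that is a coordinate error.
#'
#' BAM input requires the Rsamtools package (converted to SAM in a tempfile).
#'
#' @param path SAM (or BAM) file.
#' @param genomes A `genome_set`.
#' @return data.frame of reads: `qname`, `contig`, `start`, `end`, `strand`,
#'   `read_length`, `hit_count`.
#' @export
read_alignments <- function(path, genomes) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      stop("reading BAM requires the Rsamtools package; convert to SAM first")
    }
    sam <- tempfile(fileext = ".sam")
    Rsamtools::asSam(path, sub("\\.sam$", "", sam), overwrite = TRUE)
    on.exit(unlink(sam))
    path <- sam
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  empty <- data.frame(qname = character(), contig = character(),
                      start = integer(), end = integer(), strand = character(),
                      read_length = integer(), hit_count = integer(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 11L)
  if (length(bad)) stop("malformed SAM record (fewer than 11 fields) in '",
                        path, "'")
  flag <- vapply(parts, function(p) as.integer(p[2L]), integer(1))
  mapped <- bitwAnd(flag, 4L) == 0L
  parts <- parts[mapped]; flag <- flag[mapped]
  if (length(parts) == 0L) return(empty)
  contig <- vapply(parts, `[[`, character(1), 3L)
  pos <- vapply(parts, function(p) as.integer(p[4L]), integer(1))
  mapq <- vapply(parts, function(p) as.integer(p[5L]), integer(1))
  cigar <- vapply(parts, `[[`, character(1), 6L)
  span <- cigar_ref_span(cigar)
  qlen <- vapply(parts, function(p) {
    s <- p[10L]
    if (s == "*") NA_integer_ else nchar(s)
  }, integer(1))
  if (anyNA(span)) {
    span[is.na(span)] <- qlen[is.na(span)]
  }
  if (any(!is.na(qlen) & qlen != span)) {
    warning("reads with indels in '", basename(path),
            "': using reference span as read length")
  }
  nh <- vapply(parts, function(p) {
    if (length(p) > 11L) {
      tg <- grep("^NH:i:", p[12:length(p)], value = TRUE)
      if (length(tg)) return(as.integer(sub("^NH:i:", "", tg[1L])))
    }
    NA_integer_
  }, integer(1))
  if (anyNA(nh)) {
    warning("records without NH tag in '", basename(path),
            "': treating MAPQ == 0 as multimapped")
    nh[is.na(nh)] <- ifelse(mapq[is.na(nh)] == 0L, 2L, 1L)
  }
  strand <- ifelse(bitwAnd(flag, 16L) != 0L, "-", "+")
  start <- pos - 1L
  end <- start + span
  for (ct in unique(contig)) {
    g <- get_contig(genomes, ct)
    idx <- contig == ct
    if (!g$circular && any(end[idx] > g$length)) {
      stop_coord("alignment exceeds linear contig '", ct, "' in '", path, "'")
    }
  }
  data.frame(qname = vapply(parts, `[[`, character(1), 1L),
             contig = contig, start = start, end = end, strand = strand,
             read_length = span, hit_count = nh, stringsAsFactors = FALSE)
}

#' Write reads as a minimal valid SAM file
#'
#' Emits an `@HD`/`@SQ` header and one ungapped record per read with an
#' `NH:i` tag. Sequences are filled in from the genome (forward strand, as
#' SAM stores reads on the reference strand). On circular contigs,
#' origin-spanning reads keep their unwrapped span (POS near the contig end,
#' CIGAR running past it) — a documented convention of this package's
#' synthetic SAM, handled by [read_alignments()].
#'
#' @param reads Read data.frame (see [read_alignments()]).
#' @param genomes A `genome_set`.
#' @param path Output file.
#' @export
write_sam <- function(reads, genomes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (g in genomes) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", g$contig_id, g$length), con)
  }
  if (nrow(reads) > 0L) {
    seqs <- vapply(seq_len(nrow(reads)), function(i) {
      extract_sequence(reads$contig[i], reads$start[i], reads$end[i], "+",
                       genomes)
    }, character(1))
    recs <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNH:i:%d",
                    reads$qname, ifelse(reads$strand == "-", 16L, 0L),
                    reads$contig, reads$start + 1L, reads$end - reads$start,
                    seqs, reads$hit_count)
    writeLines(recs, con)
  }
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated with header columns `library_id`, `method` (RIBO or RNA),
#' `condition`, `replicate`, `path`. (method, condition, replicate) triples
#' must be unique.
#'
#' @param path TSV file.
#' @param base_dir Directory against which relative `path` entries are
#'   resolved (default: the sheet's own directory).
#' @return data.frame of class `sample_sheet`.
#' @export
read_sample_sheet <- function(path, base_dir = dirname(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("library_id", "method", "condition", "replicate", "path")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("sample sheet '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  validate_sample_sheet(df)
  rel <- !grepl("^/", df$path)
  df$path[rel] <- file.path(base_dir, df$path[rel])
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Validate a sample sheet data.frame
#'
#' @param df data.frame with the sample-sheet columns.
#' @return The data.frame, invisibly; errors on violations.
#' @export
validate_sample_sheet <- function(df) {
  if (!all(df$method %in% c("RIBO", "RNA"))) {
    stop("sample sheet: method must be RIBO or RNA")
  }
  if (any(df$replicate < 1)) stop("sample sheet: replicate must be >= 1")
  key <- paste(df$method, df$condition, df$replicate)
  if (anyDuplicated(key)) {
    stop("sample sheet: duplicate (method, condition, replicate) triple: ",
         key[duplicated(key)][1L])
  }
  invisible(df)
}
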