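# Merging ORF predictions with the reference annotation.
#
# Identity of an ORF is its (contig, strand, stop anchor, start) after wrap
# normalisation: two records merge iff start and stop match exactly.
# Same-stop/different-start predictions stay separate — alternative start
# sites are biologically meaningful in Ribo-seq. Novelty means no annotated
# CDS shares the key.

#' Canonical identity key of an ORF
#'
#' The stop anchor is the ORF's final nucleotide (`end - 1` wrapped on the
#' plus strand; `start` on the minus strand). Keys are equal for wrapped and
#' unwrapped encodings of the same origin-spanning ORF.
#'
#' @param orfs Feature data.frame.
#' @param genomes A `genome_set`.
#' @return Character vector `contig|strand|stop|start`.
#' @export
orf_key <- function(orfs, genomes) {
  vapply(seq_len(nrow(orfs)), function(i) {
    g <- get_contig(genomes, orfs$contig[i])
    len <- g$length
    s <- orfs$start[i] %% len
    e1 <- (orfs$end[i] - 1L) %% len
    if (orfs$strand[i] == "+") {
      sprintf("%s|%s|%d|%d", orfs$contig[i], "+", e1, s)
    } else {
      sprintf("%s|%s|%d|%d", orfs$contig[i], "-", s, e1)
    }
  }, character(1))
}

# canonical unwrapped coordinates for a key: start wrapped into [0, len)
canonicalize_interval <- function(orfs, genomes) {
  for (i in seq_len(nrow(orfs))) {
    g <- get_contig(genomes, orfs$contig[i])
    w <- orfs$end[i] - orfs$start[i]
    s <- orfs$start[i] %% g$length
    orfs$start[i] <- s
    orfs$end[i] <- s + w
  }
  orfs
}

#' Merge annotation and predictor ORF sets into a non-redundant list
#'
#' One merged record per distinct [orf_key()]; detection evidence accumulates
#' every source (the annotation contributes `tool = "annotation"` evidence).
#' Coordinates come from the annotation record when present, else from the
#' first prediction carrying the key, canonicalised to wrapped-start form.
#' Output order is deterministic: (contig, wrapped start, strand). Merging is
#' idempotent and invariant under permutation of prediction sets (duplicate
#' evidence entries collapse).
#'
#' @param annotation Feature data.frame of annotated CDS (rows with
#'   `type == "CDS"` define novelty; other rows are ignored here).
#' @param prediction_sets list of lists with fields `tool`, `condition`,
#'   `replicate`, `orfs` (feature data.frame, `score` column optional).
#' @param genomes A `genome_set`.
#' @return data.frame of class `merged_orfs`: `orf_id`, `contig`, `start`,
#'   `end`, `strand`, `novelty`, `evidence` (canonical
#'   `tool:condition:replicate[:score]` entries, `;`-joined), `n_evidence`.
#' @export
merge_predictions <- function(annotation, prediction_sets, genomes) {
  ann <- annotation[annotation$type == "CDS", , drop = FALSE]
  recs <- list()
  if (nrow(ann) > 0L) {
    ann <- canonicalize_interval(ann, genomes)
    recs[[1L]] <- data.frame(
      key = orf_key(ann, genomes), contig = ann$contig, start = ann$start,
      end = ann$end, strand = ann$strand, orf_id = ann$orf_id,
      tool = "annotation", condition = "", replicate = NA_integer_,
      score = NA_real_, from_annotation = TRUE, stringsAsFactors = FALSE)
  }
  for (ps in prediction_sets) {
    po <- ps$orfs
    if (nrow(po) == 0L) next
    po <- canonicalize_interval(po, genomes)
    recs[[length(recs) + 1L]] <- data.frame(
      key = orf_key(po, genomes), contig = po$contig, start = po$start,
      end = po$end, strand = po$strand, orf_id = po$orf_id,
      tool = ps$tool, condition = ps$condition,
      replicate = as.integer(ps$replicate),
      score = if ("score" %in% names(po)) po$score else NA_real_,
      from_annotation = FALSE, stringsAsFactors = FALSE)
  }
  if (length(recs) == 0L) {
    out <- data.frame(orf_id = character(), contig = character(),
                      start = integer(), end = integer(), strand = character(),
                      novelty = logical(), evidence = character(),
                      n_evidence = integer(), stringsAsFactors = FALSE)
    class(out) <- c("merged_orfs", "data.frame")
    return(out)
  }
  all <- do.call(rbind, recs)
  keys <- unique(all$key)
  rows <- lapply(keys, function(k) {
    grp <- all[all$key == k, , drop = FALSE]
    ai <- which(grp$from_annotation)
    ref <- if (length(ai)) grp[ai[1L], ] else grp[1L, ]
    ev <- unique(data.frame(tool = grp$tool, condition = grp$condition,
                            replicate = grp$replicate, score = grp$score,
                            stringsAsFactors = FALSE))
    ev <- ev[order(ev$tool, ev$condition, ev$replicate), , drop = FALSE]
    ev_str <- paste(vapply(seq_len(nrow(ev)), function(j) {
      base <- if (ev$tool[j] == "annotation") "annotation" else
        sprintf("%s:%s:%d", ev$tool[j], ev$condition[j], ev$replicate[j])
      if (!is.na(ev$score[j])) paste0(base, ":", format(ev$score[j])) else base
    }, character(1)), collapse = ";")
    data.frame(orf_id = ref$orf_id, contig = ref$contig, start = ref$start,
               end = ref$end, strand = ref$strand,
               novelty = length(ai) == 0L, evidence = ev_str,
               n_evidence = nrow(ev), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$start, out$strand, out$end), , drop = FALSE]
  # deterministic ids for novel ORFs without stable names
  novel_na <- out$novelty & (is.na(out$orf_id) | !nzchar(out$orf_id))
  out$orf_id[novel_na] <- sprintf("novel_%s_%d_%s", out$contig[novel_na],
                                  out$start[novel_na], out$strand[novel_na])
  if (anyDuplicated(out$orf_id)) {
    dup <- duplicated(out$orf_id)
    out$orf_id[dup] <- paste0(out$orf_id[dup], "_",
                              out$start[dup], out$strand[dup])
  }
  rownames(out) <- NULL
  class(out) <- c("merged_orfs", "data.frame")
  out
}

#' Enrich merged ORFs with sequence-derived features
#'
#' Fills `start_codon` (first 3 nt in reading direction), `sequence`,
#' `length_nt` and `length_aa` (`length_nt/3 - 1` when the length is a
#' multiple of 3, i.e. the stop codon is included; NA otherwise).
#'
#' @param merged `merged_orfs` data.frame.
#' @param genomes A `genome_set`.
#' @return The data.frame with the extra columns.
#' @export
annotate_features <- function(merged, genomes) {
  n <- nrow(merged)
  seqs <- character(n); sc <- character(n)
  for (i in seq_len(n)) {
    w <- merged$end[i] - merged$start[i]
    if (w < 6L) {
      stop("malformed ORF '", merged$orf_id[i], "': length ", w,
           " nt is shorter than 6 nt")
    }
    seqs[i] <- extract_sequence(merged$contig[i], merged$start[i],
                                merged$end[i], merged$strand[i], genomes)
    sc[i] <- substr(seqs[i], 1L, 3L)
  }
  merged$start_codon <- sc
  merged$sequence <- seqs
  merged$length_nt <- merged$end - merged$start
  merged$length_aa <- ifelse(merged$length_nt %% 3L == 0L,
                             merged$length_nt %/% 3L - 1L, NA_integer_)
  merged
}

#' Write merged ORFs to GFF3
#'
#' Attributes carry `ID`, `novelty`, `evidence` and (when present)
#' `start_codon`; origin-spanning ORFs are wrapped per [write_gff3()].
#'
#' @param merged `merged_orfs` data.frame (optionally annotated).
#' @param path Output file.
#' @param genomes A `genome_set`.
#' @export
write_merged_gff3 <- function(merged, path, genomes) {
  attrs <- sprintf("ID=%s;novelty=%s;evidence=%s", merged$orf_id,
                   ifelse(merged$novelty, "true", "false"), merged$evidence)
  if ("start_codon" %in% names(merged)) {
    attrs <- paste0(attrs, ";start_codon=", merged$start_codon)
  }
  df <- data.frame(orf_id = merged$orf_id, contig = merged$contig,
                   start = merged$start, end = merged$end,
                   strand = merged$strand, type = "CDS", source = "riboloop",
                   score = NA_real_, attributes = attrs,
                   stringsAsFactors = FALSE)
  write_gff3(df, path, genomes)
}
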