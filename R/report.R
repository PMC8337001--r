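# The enriched overview table: one row per merged ORF joining coordinates,
# novelty, sequence features, per-library expression, per-condition TE,
# detection evidence and optional external differential-expression results.

#' Left-join external differential-expression tables onto merged ORFs
#'
#' DE tables come from external tools; each table is keyed either by
#' `orf_id` or by coordinates (`contig`, `start`, `end`, `strand`, internal
#' 0-based half-open — matched through [orf_key()] so wrapped/unwrapped
#' encodings of origin-spanning ORFs join correctly). Every ORF is retained;
#' unmatched DE rows are reported, never duplicated into the output.
#'
#' @param merged `merged_orfs` data.frame.
#' @param de_tables list of lists with fields `contrast` and `table` (a
#'   data.frame with `log2FC` and `padj` plus a key).
#' @param genomes A `genome_set`.
#' @return list: `de` (data.frame of per-contrast columns
#'   `<contrast>_log2FC`, `<contrast>_padj`, aligned to `merged` rows),
#'   `unmatched` (data.frame contrast/key of DE rows with no ORF).
#' @export
join_differential <- function(merged, de_tables, genomes) {
  de <- data.frame(row.names = seq_len(nrow(merged)))
  unmatched <- data.frame(contrast = character(), key = character(),
                          stringsAsFactors = FALSE)
  if (length(de_tables) == 0L) return(list(de = de, unmatched = unmatched))
  mkey <- orf_key(merged, genomes)
  for (dt in de_tables) {
    tab <- dt$table
    if (all(c("contig", "start", "end", "strand") %in% names(tab))) {
      key <- orf_key(tab, genomes)
      target <- mkey
    } else if ("orf_id" %in% names(tab)) {
      key <- tab$orf_id
      target <- merged$orf_id
    } else {
      stop("DE table for contrast '", dt$contrast,
           "' has neither orf_id nor coordinate columns")
    }
    if (anyDuplicated(key)) {
      stop("malformed DE table for contrast '", dt$contrast,
           "': duplicate key '", key[duplicated(key)][1L], "'")
    }
    idx <- match(target, key)
    de[[paste0(dt$contrast, "_log2FC")]] <- tab$log2FC[idx]
    de[[paste0(dt$contrast, "_padj")]] <- tab$padj[idx]
    miss <- !(key %in% target)
    if (any(miss)) {
      unmatched <- rbind(unmatched,
                         data.frame(contrast = dt$contrast, key = key[miss],
                                    stringsAsFactors = FALSE))
    }
  }
  list(de = de, unmatched = unmatched)
}

#' Assemble the per-ORF overview table
#'
#' Fixed column order: identity and coordinates (1-based `start`/`stop` as in
#' the GFF3 output, wrapped for origin-spanning ORFs), novelty and sequence
#' features, per-library `<lib>_count` / `<lib>_rpkm` / `<lib>_tpm`,
#' per-condition `TE_<condition>`, `evidence`, then per-contrast DE columns.
#' Rows are ordered (contig, start, strand); exactly one row per merged ORF.
#'
#' @param merged Annotated `merged_orfs` data.frame.
#' @param quant Result of [quantify_orfs()].
#' @param de Optional result of [join_differential()].
#' @param genomes A `genome_set`.
#' @return data.frame, one row per ORF.
#' @export
build_overview <- function(merged, quant, de = NULL, genomes) {
  extra <- setdiff(rownames(quant$counts), merged$orf_id)
  if (length(extra)) {
    stop("inconsistent inputs: orf_id '", extra[1L],
         "' present in counts but absent from merged ORFs")
  }
  ord <- order(merged$contig, merged$start, merged$strand)
  merged <- merged[ord, , drop = FALSE]
  idx <- match(merged$orf_id, rownames(quant$counts))
  start_gff <- integer(nrow(merged)); stop_gff <- integer(nrow(merged))
  for (i in seq_len(nrow(merged))) {
    len <- get_contig(genomes, merged$contig[i])$length
    start_gff[i] <- merged$start[i] + 1L
    stop_gff[i] <- if (merged$end[i] > len) merged$end[i] - len else merged$end[i]
  }
  out <- data.frame(orf_id = merged$orf_id, contig = merged$contig,
                    start = start_gff, stop = stop_gff,
                    strand = merged$strand, novelty = merged$novelty,
                    start_codon = merged$start_codon,
                    length_nt = merged$length_nt,
                    length_aa = merged$length_aa,
                    sequence = merged$sequence, stringsAsFactors = FALSE)
  for (lib in colnames(quant$counts)) {
    out[[paste0(lib, "_count")]] <- quant$counts[idx, lib]
    out[[paste0(lib, "_rpkm")]] <- quant$rpkm[idx, lib]
    out[[paste0(lib, "_tpm")]] <- quant$tpm[idx, lib]
  }
  for (cond in colnames(quant$te)) {
    out[[paste0("TE_", cond)]] <- quant$te[idx, cond]
  }
  out$evidence <- merged$evidence
  if (!is.null(de) && ncol(de$de) > 0L) {
    for (cn in colnames(de$de)) out[[cn]] <- de$de[ord, cn]
  }
  rownames(out) <- NULL
  out
}

#' Write the overview table as TSV
#'
#' One header line; floating-point fields printed with 4 significant digits;
#' missing values as the literal `NA`.
#'
#' @param rows Overview data.frame from [build_overview()].
#' @param path Output file.
#' @export
write_overview <- function(rows, path) {
  fmt <- rows
  for (cn in names(fmt)) {
    if (is.double(fmt[[cn]])) {
      fmt[[cn]] <- ifelse(is.na(fmt[[cn]]), NA,
                          format(signif(fmt[[cn]], 4), trim = TRUE,
                                 scientific = FALSE))
    }
  }
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read an external DE result TSV
#'
#' Expected columns: a key (`orf_id`, or `contig`/`start`/`end`/`strand`)
#' plus `log2FC` and `padj`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_de_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("log2FC", "padj") %in% names(df))) {
    stop("DE table '", path, "' must have log2FC and padj columns")
  }
  df
}
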