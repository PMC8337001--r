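# Shared in-code fixtures for the test suite.

tiny_genome <- function(sequence = "ATGAAATAGCCGGTTAACCG", circular = FALSE,
                        contig_id = "chr") {
  genome_sequence(contig_id, sequence, circular = circular)
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

make_reads <- function(start, end, strand = "+", hit_count = 1L,
                       contig = "chr") {
  n <- max(length(start), length(end))
  data.frame(qname = sprintf("r%d", seq_len(n)), contig = rep_len(contig, n),
             start = as.integer(start), end = as.integer(end),
             strand = rep_len(strand, n),
             read_length = as.integer(end - start),
             hit_count = rep_len(as.integer(hit_count), n),
             stringsAsFactors = FALSE)
}

# random read set on one contig; reads may span the origin when circular
random_reads <- function(genome, n, min_len = 2L, max_len = 8L) {
  len <- genome$length
  rl <- sample.int(max_len - min_len + 1L, n, replace = TRUE) + min_len - 1L
  s <- if (genome$circular) sample.int(len, n, replace = TRUE) - 1L
       else sample.int(len - max_len, n, replace = TRUE) - 1L
  make_reads(s, s + rl, strand = sample(c("+", "-"), n, replace = TRUE),
             contig = genome$contig_id)
}

make_orfs <- function(start, end, strand = "+", orf_id = NULL, type = "CDS",
                      contig = "chr", source = "test") {
  n <- max(length(start), length(end))
  if (is.null(orf_id)) orf_id <- sprintf("orf%d", seq_len(n))
  data.frame(orf_id = orf_id, contig = rep_len(contig, n),
             start = as.integer(start), end = as.integer(end),
             strand = rep_len(strand, n), type = rep_len(type, n),
             source = rep_len(source, n), score = rep_len(NA_real_, n),
             attributes = sprintf("ID=%s", orf_id), stringsAsFactors = FALSE)
}
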