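# Independent brute-force oracles: every one enumerates positions one
# nucleotide at a time with explicit modular wrap, never reusing package
# internals beyond the plain data structures.

# ordered forward-strand positions covered by [start, end) with wrap
oracle_positions <- function(start, end, len) {
  p <- integer(0)
  i <- start
  while (i < end) {
    p <- c(p, ((i %% len) + len) %% len)
    i <- i + 1L
  }
  p
}

# biological-order position list of a read (5' -> 3')
oracle_bio_positions <- function(start, end, strand, len) {
  p <- oracle_positions(start, end, len)
  if (strand == "-") rev(p) else p
}

# anchor by enumerating the biological position list
oracle_anchor <- function(start, end, strand, len, mode) {
  b <- oracle_bio_positions(start, end, strand, len)
  L <- length(b)
  switch(mode,
         fiveprime = b[1L],
         threeprime = b[L],
         center = b[((L - 1L) %/% 2L) + 1L])
}

# full per-position coverage by stepping through every read
oracle_full_coverage <- function(reads, len, strand) {
  v <- numeric(len)
  for (i in seq_len(nrow(reads))) {
    if (reads$strand[i] != strand) next
    for (p in oracle_positions(reads$start[i], reads$end[i], len)) {
      v[p + 1L] <- v[p + 1L] + 1
    }
  }
  v
}

oracle_anchor_coverage <- function(reads, len, strand, mode) {
  v <- numeric(len)
  for (i in seq_len(nrow(reads))) {
    if (reads$strand[i] != strand) next
    a <- oracle_anchor(reads$start[i], reads$end[i], reads$strand[i], len,
                       mode)
    v[a + 1L] <- v[a + 1L] + 1
  }
  v
}

# do two intervals share any wrapped position?
oracle_overlap <- function(s1, e1, s2, e2, len) {
  length(intersect(oracle_positions(s1, e1, len),
                   oracle_positions(s2, e2, len))) > 0L
}

# (read x window) incidence count: tests every read against every window
oracle_metagene_mass <- function(reads, starts, len, up, down, read_lengths,
                                 circular, anchor_mode = "fiveprime") {
  mass <- 0L
  for (i in seq_len(nrow(reads))) {
    if (!(reads$read_length[i] %in% read_lengths)) next
    a <- oracle_anchor(reads$start[i], reads$end[i], reads$strand[i], len,
                       anchor_mode)
    for (j in seq_len(nrow(starts))) {
      if (reads$strand[i] != starts$strand[j] ||
          reads$contig[i] != starts$contig[j]) next
      win <- vapply(seq.int(-up, down - 1L), function(o) {
        g <- if (starts$strand[j] == "+") starts$pos[j] + o
             else starts$pos[j] - o
        if (circular) ((g %% len) + len) %% len else g
      }, numeric(1))
      if (a %in% win) mass <- mass + 1L
    }
  }
  mass
}
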