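# ORF merging, novelty classification and feature annotation.

test_that("orf_key: identity, isoforms, wrap equivalence", {
  g <- genome_sequence("chr", random_seq(10), circular = TRUE)
  gs <- genome_set(list(g))
  a <- make_orfs(2, 8, orf_id = "a")
  b <- make_orfs(2, 8, orf_id = "b", source = "other")
  expect_identical(orf_key(a, gs), orf_key(b, gs))
  # same stop, different start -> distinct isoform keys
  iso <- make_orfs(4, 8, orf_id = "c")
  expect_false(orf_key(a, gs) == orf_key(iso, gs))
  # wrapped and unwrapped encodings of an origin-spanning ORF agree
  unwrapped <- make_orfs(8, 14, orf_id = "d")
  rewrapped <- make_orfs(-2, 4, orf_id = "e")   # negative-coordinate form
  expect_identical(orf_key(unwrapped, gs), orf_key(rewrapped, gs))
})

test_that("merge_predictions: evidence accumulation and novelty", {
  g <- genome_sequence("chr", random_seq(200))
  gs <- genome_set(list(g))
  ann <- make_orfs(10, 40, orf_id = "geneA")
  predA <- list(tool = "deepribo", condition = "c1", replicate = 1,
                orfs = make_orfs(10, 40, orf_id = "p1"))
  m <- merge_predictions(ann, list(predA), gs)
  expect_equal(nrow(m), 1)
  expect_false(m$novelty)
  expect_equal(m$n_evidence, 2L)
  expect_equal(m$orf_id, "geneA")      # annotation coordinates/id win

  m2 <- merge_predictions(ann[0, ], list(list(tool = "reparation",
                                              condition = "c1", replicate = 1,
                                              orfs = make_orfs(50, 80,
                                                               orf_id = "pB"))),
                          gs)
  expect_true(m2$novelty)
  expect_equal(m2$n_evidence, 1L)
})

test_that("merging is idempotent and permutation/duplication invariant (property)", {
  set.seed(444)
  for (i in 1:20) {
    len <- sample(60:120, 1)
    g <- genome_sequence("chr", random_seq(len), circular = TRUE)
    gs <- genome_set(list(g))
    n_ann <- sample(0:4, 1)
    mk <- function(n) {
      s <- sample(0:(len - 1), n, replace = TRUE)
      w <- 3 * sample(4:10, n, replace = TRUE)
      # randomly emit wrapped (negative-start) encodings of the same ORF
      wrapped <- runif(n) < 0.3
      s <- ifelse(wrapped, s - len, s)
      make_orfs(s, s + w, strand = sample(c("+", "-"), n, replace = TRUE),
                orf_id = sprintf("x%d_%d", i, seq_len(max(n, 1)))[seq_len(n)])
    }
    ann <- mk(n_ann)
    sets <- lapply(1:3, function(k) {
      list(tool = sample(c("reparation", "deepribo"), 1),
           condition = "c1", replicate = k, orfs = mk(sample(1:5, 1)))
    })
    m <- merge_predictions(ann, sets, gs)
    # distinct-key conservation against a set oracle
    all_keys <- unique(c(if (nrow(ann)) orf_key(ann, gs),
                         unlist(lapply(sets, function(s)
                           orf_key(s$orfs, gs)))))
    expect_equal(nrow(m), length(all_keys))
    # permutation invariance
    m_perm <- merge_predictions(ann, rev(sets), gs)
    expect_equal(m_perm[c("contig", "start", "end", "strand", "novelty",
                          "evidence")],
                 m[c("contig", "start", "end", "strand", "novelty",
                     "evidence")])
    # duplicating a prediction set collapses duplicate evidence
    m_dup <- merge_predictions(ann, c(sets, sets[1]), gs)
    expect_equal(m_dup$evidence, m$evidence)
    # every annotated ORF appears with novelty FALSE
    if (nrow(ann)) {
      expect_true(all(!m$novelty[match(orf_key(ann, gs),
                                       orf_key(m, gs))]))
    }
  }
})

test_that("annotate_features fills sequence-derived columns, with wrap", {
  seqs <- paste0("ATGAAATAG", random_seq(21))
  g <- genome_sequence("chr", seqs, circular = TRUE)
  gs <- genome_set(list(g))
  m <- merge_predictions(make_orfs(0, 9, orf_id = "g1"), list(), gs)
  m <- annotate_features(m, gs)
  expect_equal(m$start_codon, "ATG")
  expect_equal(m$length_aa, 2L)
  expect_equal(m$sequence, "ATGAAATAG")
  # minus strand: first 3 nt of the reverse complement
  m2 <- annotate_features(
    merge_predictions(make_orfs(0, 9, strand = "-", orf_id = "g2"),
                      list(), gs), gs)
  expect_equal(m2$start_codon, substr(riboloop:::revcomp("ATGAAATAG"), 1, 3))
  # origin-spanning ORF sequence matches the wrap-around oracle
  m3 <- annotate_features(
    merge_predictions(make_orfs(24, 33, orf_id = "g3"), list(), gs), gs)
  expect_equal(m3$sequence,
               paste0(substr(seqs, 25, 30), substr(seqs, 1, 3)))
  expect_error(annotate_features(
    merge_predictions(make_orfs(0, 5, orf_id = "tiny"), list(), gs), gs),
    "malformed ORF")
})

test_that("merged GFF3 output round-trips coordinates and attributes", {
  g <- genome_sequence("chr", random_seq(60), circular = TRUE)
  gs <- genome_set(list(g))
  ann <- make_orfs(c(10, 55), c(31, 70), orf_id = c("g1", "g2"))
  m <- annotate_features(merge_predictions(ann, list(), gs), gs)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_merged_gff3(m, f, gs)
  back <- read_gff3(f, gs)
  expect_equal(back[c("start", "end", "strand")],
               m[c("start", "end", "strand")], ignore_attr = TRUE)
  expect_equal(gff_attr(back$attributes, "novelty"), c("false", "false"))
  expect_equal(gff_attr(back$attributes, "start_codon"), m$start_codon)
})
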