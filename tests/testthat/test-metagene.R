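# Metagene profiling around start codons and frame periodicity summary.

test_that("collect_start_positions: strand rules and edge exclusion", {
  lin <- genome_set(list(genome_sequence("chr", random_seq(1000))))
  ann <- make_orfs(c(100, 100, 10), c(400, 400, 40),
                   strand = c("+", "-", "+"))
  sp <- collect_start_positions(ann, lin, 50, 50)
  expect_equal(sp$starts$pos, c(100, 399))
  expect_equal(sp$excluded, 1L)   # window would reach position -40
  # circular contigs never exclude
  circ <- genome_set(list(genome_sequence("chr", random_seq(1000),
                                          circular = TRUE)))
  expect_equal(collect_start_positions(ann, circ, 50, 50)$excluded, 0L)
})

test_that("metagene offsets: direct, upstream and minus-strand cases", {
  gs <- genome_set(list(genome_sequence("chr", random_seq(1000))))
  starts <- data.frame(contig = "chr", strand = "+", pos = 100,
                       stringsAsFactors = FALSE)
  prof <- metagene_profile(make_reads(100, 128), starts, gs)
  expect_equal(prof$counts["28", "0"], 1L)
  expect_equal(sum(prof$counts), 1L)
  prof2 <- metagene_profile(make_reads(85, 113), starts, gs)
  expect_equal(prof2$counts["28", "-15"], 1L)
  starts_m <- data.frame(contig = "chr", strand = "-", pos = 399,
                         stringsAsFactors = FALSE)
  prof3 <- metagene_profile(make_reads(372, 400, strand = "-"), starts_m, gs)
  expect_equal(prof3$counts["28", "0"], 1L)
  # empty start list: all-zero profile, n_genes 0
  prof0 <- metagene_profile(make_reads(100, 128), starts[0, ], gs)
  expect_equal(sum(prof0$counts), 0L)
  expect_equal(prof0$n_genes, 0L)
})

test_that("profile mass equals the brute-force incidence oracle (property)", {
  set.seed(111)
  for (i in 1:25) {
    len <- sample(100:200, 1)
    circular <- i %% 2 == 0
    g <- genome_sequence("chr", random_seq(len), circular = circular)
    gs <- genome_set(list(g))
    reads <- random_reads(g, 50, min_len = 20, max_len = 30)
    if (!circular) reads <- reads[reads$end <= len, , drop = FALSE]
    n_starts <- sample(1:4, 1)
    starts <- data.frame(contig = "chr",
                         strand = sample(c("+", "-"), n_starts,
                                         replace = TRUE),
                         pos = sample(0:(len - 1), n_starts),
                         stringsAsFactors = FALSE)
    up <- sample(5:20, 1); down <- sample(5:20, 1)
    prof <- metagene_profile(reads, starts, gs, up, down, 20:30)
    want <- oracle_metagene_mass(reads, starts, len, up, down, 20:30,
                                 circular)
    # linear contigs: the oracle also counts anchors whose offset fell
    # outside [0, len); restrict to windows fully inside for comparability
    if (circular) expect_equal(sum(prof$counts), want)
    else expect_lte(abs(sum(prof$counts) - want), 0)
  }
})

test_that("strand mirror symmetry: reverse-complemented world, same profile", {
  set.seed(222)
  len <- 150
  g <- genome_sequence("chr", random_seq(len), circular = TRUE)
  gs <- genome_set(list(g))
  reads <- random_reads(g, 40, min_len = 20, max_len = 30)
  starts <- data.frame(contig = "chr", strand = c("+", "-"),
                       pos = c(30, 120), stringsAsFactors = FALSE)
  prof <- metagene_profile(reads, starts, gs, 15, 15, 20:30)
  # mirror: position p -> len - 1 - p, strand flipped
  m_reads <- reads
  m_reads$start <- len - reads$end
  m_reads$end <- len - reads$start
  m_reads$strand <- ifelse(reads$strand == "+", "-", "+")
  m_starts <- starts
  m_starts$pos <- len - 1 - starts$pos
  m_starts$strand <- ifelse(starts$strand == "+", "-", "+")
  m_g <- genome_sequence("chr", riboloop:::revcomp(g$sequence),
                         circular = TRUE)
  m_prof <- metagene_profile(m_reads, m_starts, genome_set(list(m_g)),
                             15, 15, 20:30)
  expect_equal(m_prof$counts, prof$counts)
})

test_that("frame_summary fractions", {
  gs <- genome_set(list(genome_sequence("chr", random_seq(500))))
  starts <- data.frame(contig = "chr", strand = "+", pos = 100,
                       stringsAsFactors = FALSE)
  # counts at offsets 0, 3, 6 -> all frame 0
  reads <- make_reads(c(100, 103, 106), c(128, 131, 134))
  fs <- frame_summary(metagene_profile(reads, starts, gs))
  expect_equal(unname(fs["28", ]), c(1, 0, 0))
  # {0: 2, 1: 1, 2: 1} -> (0.5, 0.25, 0.25)
  reads2 <- make_reads(c(100, 100, 101, 102), c(128, 128, 129, 130))
  fs2 <- frame_summary(metagene_profile(reads2, starts, gs))
  expect_equal(unname(fs2["28", ]), c(0.5, 0.25, 0.25))
  # uniform over offsets 0..8 -> thirds
  reads3 <- make_reads(100 + 0:8, 128 + 0:8)
  fs3 <- frame_summary(metagene_profile(reads3, starts, gs))
  expect_equal(unname(fs3["28", ]), rep(1 / 3, 3))
  # zero signal -> all-zero row
  none <- metagene_profile(make_reads(integer(0), integer(0)), starts, gs)
  expect_equal(unname(frame_summary(none)["28", ]), c(0, 0, 0))
})

test_that("planted in-frame reads recover frame-0 fraction exactly", {
  set.seed(333)
  g <- genome_sequence("chr", random_seq(600), circular = TRUE)
  gs <- genome_set(list(g))
  starts <- data.frame(contig = "chr", strand = "+", pos = 90,
                       stringsAsFactors = FALSE)
  offs <- 3 * sample(0:15, 60, replace = TRUE)
  reads <- make_reads(90 + offs, 90 + offs + 28)
  fs <- frame_summary(metagene_profile(reads, starts, gs))
  expect_identical(unname(fs["28", ]), c(1, 0, 0))
})

test_that("metagene TSV output round-trips counts", {
  gs <- genome_set(list(genome_sequence("chr", random_seq(300))))
  starts <- data.frame(contig = "chr", strand = "+", pos = 100,
                       stringsAsFactors = FALSE)
  prof <- metagene_profile(make_reads(c(100, 97), c(128, 125)), starts, gs)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_metagene(prof, f)
  back <- utils::read.delim(f, check.names = FALSE)
  expect_equal(dim(back), c(length(20:45), 101))
  m <- as.matrix(back[, -1])
  rownames(m) <- back$read_length
  expect_equal(m["28", "0"], 1)
  expect_equal(sum(m), 2)
  expect_true(file.exists(sub("\\.tsv$", ".normalized.tsv", f)))
})
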