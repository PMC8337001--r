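# Domain types, circular coordinate arithmetic and format I/O.

test_that("normalize_coordinate wraps circular and guards linear contigs", {
  circ <- genome_sequence("c", random_seq(10), circular = TRUE)
  lin <- genome_sequence("l", random_seq(10), circular = FALSE)
  expect_identical(normalize_coordinate(-2, circ), 8)
  expect_identical(normalize_coordinate(25, circ), 5)
  expect_identical(normalize_coordinate(3, lin), 3)
  expect_error(normalize_coordinate(10, lin), class = "riboloop_coordinate_error")
  expect_error(normalize_coordinate(-1, lin), "linear contig 'l'")
})

test_that("normalize_coordinate is a modular homomorphism (property)", {
  set.seed(101)
  for (i in 1:50) {
    len <- sample(5:200, 1)
    g <- genome_sequence("c", random_seq(len), circular = TRUE)
    p <- sample(-500:500, 1)
    k <- sample(-3:3, 1)
    np <- normalize_coordinate(p, g)
    expect_gte(np, 0)
    expect_lt(np, len)
    expect_identical(np, normalize_coordinate(p + k * len, g))
  }
})

test_that("unwrap_interval canonicalizes wrapped and negative coordinates", {
  circ <- genome_sequence("c", random_seq(10), circular = TRUE)
  lin <- genome_sequence("l", random_seq(10), circular = FALSE)

  iv <- unwrap_interval(8, 3, "+", circ)
  expect_equal(c(iv$start, iv$end), c(8, 13))
  # oracle: covered position sets agree
  expect_setequal(oracle_positions(iv$start, iv$end, 10), c(8, 9, 0, 1, 2))

  iv2 <- unwrap_interval(-2, 4, "+", circ)
  expect_equal(c(iv2$start, iv2$end), c(8, 14))
  expect_setequal(oracle_positions(iv2$start, iv2$end, 10),
                  c(8, 9, 0, 1, 2, 3))

  iv3 <- unwrap_interval(0, 9, "+", lin)
  expect_equal(c(iv3$start, iv3$end), c(0, 9))
  expect_error(unwrap_interval(5, 3, "+", lin), "malformed annotation")
})

test_that("extract_sequence handles strand and origin wrap", {
  g <- genome_sequence("chr", "ATGAAA", circular = TRUE)
  gs <- genome_set(list(g))
  expect_identical(extract_sequence("chr", 0, 3, "+", gs), "ATG")
  expect_identical(extract_sequence("chr", 0, 3, "-", gs), "CAT")
  # wrap-around: sequence[4:6] + sequence[1:2]
  expect_identical(extract_sequence("chr", 4, 8, "+", gs), "AAAT")
  lin <- genome_set(list(genome_sequence("chr", "ATGAAA")))
  expect_error(extract_sequence("chr", 4, 8, "+", lin),
               class = "riboloop_coordinate_error")
})

test_that("strand-flipped extraction gives exact reverse complements (property)", {
  set.seed(202)
  for (i in 1:30) {
    len <- sample(20:80, 1)
    g <- genome_sequence("chr", random_seq(len), circular = TRUE)
    gs <- genome_set(list(g))
    s <- sample(0:(len - 1), 1)
    w <- sample(1:len, 1)
    fwd <- extract_sequence("chr", s, s + w, "+", gs)
    rev <- extract_sequence("chr", s, s + w, "-", gs)
    expect_identical(nchar(fwd), w)
    expect_identical(riboloop:::revcomp(fwd), rev)
    expect_identical(riboloop:::revcomp(rev), fwd)
  }
})

test_that("GFF3 coordinate conversion and round trip, including origin-spanning", {
  g <- genome_sequence("chr", random_seq(50), circular = TRUE)
  gs <- genome_set(list(g))
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\tsrc\tCDS\t1\t3\t.\t+\t.\tID=a",
               "chr\tsrc\tCDS\t45\t6\t.\t-\t.\tID=b"), f)
  orfs <- read_gff3(f, gs)
  expect_equal(orfs$start, c(0, 44))
  expect_equal(orfs$end, c(3, 56))  # wrapped record unwrapped: 44 + 12
  f2 <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(orfs, f2, gs)
  back <- read_gff3(f2, gs)
  expect_equal(back[c("orf_id", "contig", "start", "end", "strand")],
               orfs[c("orf_id", "contig", "start", "end", "strand")])
  # wrapped emission: 1-based end < start on the origin-spanning record
  ln <- grep("ID=b", readLines(f2), value = TRUE)
  fields <- strsplit(ln, "\t")[[1]]
  expect_lt(as.integer(fields[5]), as.integer(fields[4]))
})

test_that("GFF3 round-trip preserves 1000 randomized features (property)", {
  set.seed(303)
  g_circ <- genome_sequence("circ", random_seq(300), circular = TRUE)
  g_lin <- genome_sequence("lin", random_seq(300), circular = FALSE)
  gs <- genome_set(list(g_circ, g_lin))
  n <- 1000
  contig <- sample(c("circ", "lin"), n, replace = TRUE)
  w <- sample(3:120, n, replace = TRUE)
  s <- ifelse(contig == "circ", sample(0:299, n, replace = TRUE),
              sample(0:150, n, replace = TRUE))
  orfs <- data.frame(orf_id = sprintf("f%04d", 1:n), contig = contig,
                     start = s, end = s + w, strand = sample(c("+", "-"), n,
                                                             replace = TRUE),
                     type = "CDS", source = "rand", score = NA_real_,
                     attributes = sprintf("ID=f%04d", 1:n),
                     stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(orfs, f, gs)
  back <- read_gff3(f, gs)
  expect_equal(back[c("contig", "start", "end", "strand", "orf_id")],
               orfs[c("contig", "start", "end", "strand", "orf_id")])
})

test_that("read_gff3 reports malformed records and unknown contigs", {
  gs <- genome_set(list(tiny_genome()))
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("chr\tsrc\tCDS\t1\t3\t.\t+\t."), f)  # 8 columns
  expect_error(read_gff3(f), "line 1.*9 tab-separated")
  writeLines(c("nope\tsrc\tCDS\t1\t3\t.\t+\t.\tID=x"), f)
  expect_error(read_gff3(f, gs), "unknown contig 'nope' at line 1")
})

test_that("SAM round trip: flags, NH tags, origin-spanning alignments", {
  g <- genome_sequence("chr", random_seq(40), circular = TRUE)
  gs <- genome_set(list(g))
  reads <- make_reads(c(2, 35, 10), c(12, 45, 20),
                      strand = c("+", "+", "-"), hit_count = c(1, 1, 3))
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(reads, gs, f)
  back <- read_alignments(f, gs)
  expect_equal(back[c("contig", "start", "end", "strand", "read_length",
                      "hit_count")],
               reads[c("contig", "start", "end", "strand", "read_length",
                       "hit_count")])
  # FLAG bit 16 drives strand
  raw <- readLines(f)
  rec <- strsplit(grep("^r3\t", raw, value = TRUE), "\t")[[1]]
  expect_equal(as.integer(rec[2]), 16L)
})

test_that("sample sheet reader validates structure", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("library_id\tmethod\tcondition\treplicate\tpath",
               "l1\tRIBO\tc1\t1\ta.sam",
               "l2\tRNA\tc1\t1\tb.sam"), f)
  sheet <- read_sample_sheet(f)
  expect_s3_class(sheet, "sample_sheet")
  expect_equal(nrow(sheet), 2)
  writeLines(c("library_id\tmethod\tcondition\treplicate\tpath",
               "l1\tRIBO\tc1\t1\ta.sam",
               "l2\tRIBO\tc1\t1\tb.sam"), f)
  expect_error(read_sample_sheet(f), "duplicate")
  writeLines(c("library_id\tmethod\tcondition\tpath",
               "l1\tRIBO\tc1\ta.sam"), f)
  expect_error(read_sample_sheet(f), "missing required column")
})
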