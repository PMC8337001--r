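# Self-contained synthetic fixtures: a (circular) genome with planted ORFs,
# an annotation, predictor-style ORF calls, and RIBO/RNA SAM libraries with
# planted truth (per-ORF read totals, rRNA contamination, multimappers,
# translation efficiencies). Everything is deterministic under spec$seed via
# one pseudo-random stream.
#
# What the generator emulates: footprint-length variation, 5'-end enrichment
# at start codons, three-nucleotide periodicity, rRNA contamination,
# multimapping, origin-spanning genes on circular chromosomes, and planted
# per-condition translation efficiency. What it does not: sequencing errors,
# quality scores, adapter remnants, coverage heterogeneity along ORFs beyond
# the start peak, or operonic structure.

#' Build a simulation specification
#'
#' Defaults describe a small but realistic bacterial toy world: an 8 kb
#' circular chromosome, six ORFs (one of them origin-spanning, one left out
#' of the annotation as a "novel" ORF), footprints of 26-30 nt, a 5x start
#' peak, 90% in-frame placement, 10% rRNA contamination and 5% multimappers.
#'
#' Because translation efficiency is a ratio of per-million-normalised
#' coverages, it is compositional: libraries are therefore padded with
#' intergenic background reads to equal retained depth
#' (`equalize_depth = TRUE`) so planted TE values are recovered on their
#' absolute scale.
#'
#' @param genome_length Contig length (nt).
#' @param circular Circular chromosome? When TRUE the first ORF spans the
#'   origin.
#' @param n_orfs Total ORFs planted (annotated + novel).
#' @param n_novel How many of the planted ORFs are withheld from the
#'   annotation (detectable only by predictors).
#' @param orf_length_range ORF length range in nt (rounded to codons,
#'   including start and stop).
#' @param te Named list: condition -> numeric vector of planted TE per ORF
#'   (length `n_orfs`).
#' @param n_replicates Replicates per condition and method.
#' @param reads_per_orf RNA reads per ORF per library; RIBO reads are
#'   `round(reads_per_orf * te)`.
#' @param read_length_distribution data.frame with columns `length`, `prob`
#'   (probabilities sum to 1).
#' @param start_enrichment Multiplier for 5'-end density at offset 0.
#' @param frame_prob Probability that a RIBO read's 5' end is in frame 0.
#' @param rrna_fraction Fraction of each library drawn from the planted rRNA
#'   locus.
#' @param multimap_fraction Fraction of reads tagged as multimappers
#'   (NH = 2), drawn among ORF reads.
#' @param detect_prob Per-ORF detection probability for each simulated
#'   predictor run.
#' @param equalize_depth Pad libraries with intergenic background reads to
#'   equal retained depth?
#' @param seed Integer seed for the single pseudo-random stream.
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(genome_length = 8000L, circular = TRUE,
                            n_orfs = 6L, n_novel = 1L,
                            orf_length_range = c(120L, 300L),
                            te = NULL, n_replicates = 2L,
                            reads_per_orf = 200L,
                            read_length_distribution = data.frame(
                              length = 26:30,
                              prob = c(0.1, 0.2, 0.4, 0.2, 0.1)),
                            start_enrichment = 5, frame_prob = 0.9,
                            rrna_fraction = 0.1, multimap_fraction = 0.05,
                            detect_prob = 0.9, equalize_depth = TRUE,
                            seed = 42L) {
  if (is.null(te)) te <- list(ctrl = rep(1, n_orfs))
  stopifnot(abs(sum(read_length_distribution$prob) - 1) < 1e-9,
            all(vapply(te, length, integer(1)) == n_orfs),
            all(unlist(te) > 0),
            rrna_fraction >= 0, rrna_fraction < 1,
            multimap_fraction >= 0, multimap_fraction < 1,
            n_novel < n_orfs)
  structure(list(genome_length = as.integer(genome_length),
                 circular = isTRUE(circular), n_orfs = as.integer(n_orfs),
                 n_novel = as.integer(n_novel),
                 orf_length_range = as.integer(orf_length_range), te = te,
                 n_replicates = as.integer(n_replicates),
                 reads_per_orf = as.integer(reads_per_orf),
                 read_length_distribution = read_length_distribution,
                 start_enrichment = start_enrichment, frame_prob = frame_prob,
                 rrna_fraction = rrna_fraction,
                 multimap_fraction = multimap_fraction,
                 detect_prob = detect_prob,
                 equalize_depth = isTRUE(equalize_depth),
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

SENSE_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1L, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))
STOP_CODONS <- c("TAA", "TAG", "TGA")

# stamp a forward-strand substring into a character-vector genome with wrap
stamp <- function(chars, start, s, len) {
  pos <- (seq.int(start, start + nchar(s) - 1L) %% len) + 1L
  chars[pos] <- strsplit(s, NULL)[[1L]]
  chars
}

#' Simulate a genome with planted ORFs and an rRNA locus
#'
#' Seeds the pseudo-random stream from `spec$seed`. ORFs begin with ATG and
#' end with a stop codon, are placed without overlap with generous
#' intergenic gaps, and on a circular genome the first ORF spans the origin.
#' The last `n_novel` ORFs are flagged novel (withheld from the annotation).
#' One rRNA locus and one intergenic background region are also reserved.
#'
#' @param spec A `simulation_spec`.
#' @return list: `genome` (`genome_sequence` "chr"), `orfs` (data.frame with
#'   `novel` flag), `annotation` (feature data.frame: annotated CDS + rRNA),
#'   `regions` (rRNA and background intervals).
#' @export
simulate_genome <- function(spec) {
  set.seed(spec$seed)
  len <- spec$genome_length
  gap <- 60L
  n <- spec$n_orfs
  lens <- 3L * sample(seq.int(spec$orf_length_range[1L] %/% 3L,
                              spec$orf_length_range[2L] %/% 3L),
                      n, replace = TRUE)
  rrna_len <- 120L
  bg_len <- 300L
  need <- sum(lens) + rrna_len + bg_len + gap * (n + 3L)
  if (need > len) {
    stop("infeasible packing: need ", need, " nt but genome_length is ", len)
  }
  strands <- sample(c("+", "-"), n, replace = TRUE)
  starts <- integer(n); ends <- integer(n)
  if (spec$circular) {
    starts[1L] <- len - (lens[1L] %/% 2L)
    ends[1L] <- starts[1L] + lens[1L]       # unwrapped, spans origin
    cursor <- (ends[1L] - len) + gap
    first <- 2L
  } else {
    cursor <- gap
    first <- 1L
  }
  for (i in seq.int(first, n)) {
    starts[i] <- cursor
    ends[i] <- cursor + lens[i]
    cursor <- ends[i] + gap
  }
  rrna <- c(cursor, cursor + rrna_len); cursor <- rrna[2L] + gap
  background <- c(cursor, cursor + bg_len)
  if (background[2L] + gap > (if (spec$circular) starts[1L] else len)) {
    stop("infeasible packing of rRNA/background regions")
  }
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  for (i in seq_len(n)) {
    n_codons <- lens[i] %/% 3L
    body <- paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
                  collapse = "")
    orf_seq <- paste0("ATG", body, sample(STOP_CODONS, 1L))
    fwd <- if (strands[i] == "+") orf_seq else revcomp(orf_seq)
    chars <- stamp(chars, starts[i], fwd, len)
  }
  genome <- genome_sequence("chr", paste(chars, collapse = ""),
                            circular = spec$circular)
  novel <- c(rep(FALSE, n - spec$n_novel), rep(TRUE, spec$n_novel))
  orf_ids <- sprintf("orf%02d", seq_len(n))
  orfs <- data.frame(orf_id = orf_ids, contig = "chr", start = starts,
                     end = ends, strand = strands, type = "CDS",
                     source = "simulation", score = NA_real_,
                     attributes = paste0("ID=", orf_ids),
                     novel = novel, stringsAsFactors = FALSE)
  ann <- orfs[!orfs$novel, names(orfs) != "novel", drop = FALSE]
  ann <- rbind(ann, data.frame(orf_id = "rrna01", contig = "chr",
                               start = rrna[1L], end = rrna[2L], strand = "+",
                               type = "rRNA", source = "simulation",
                               score = NA_real_, attributes = "ID=rrna01",
                               stringsAsFactors = FALSE))
  rownames(ann) <- NULL
  list(genome = genome, orfs = orfs, annotation = ann,
       regions = list(rrna = rrna, background = background))
}

# draw read lengths from the spec's distribution
draw_lengths <- function(spec, n) {
  d <- spec$read_length_distribution
  sample(d$length, n, replace = TRUE, prob = d$prob)
}

# place n reads of a library inside one ORF; returns a read data.frame
place_orf_reads <- function(spec, orf, n, method, len) {
  if (n == 0L) {
    return(NULL)
  }
  rl <- draw_lengths(spec, n)
  L <- orf$end - orf$start
  if (method == "RIBO") {
    inframe <- seq.int(0L, L - 9L, by = 3L)
    w <- rep(1, length(inframe)); w[1L] <- spec$start_enrichment
    off <- sample(inframe, n, replace = TRUE, prob = w)
    shift <- ifelse(stats::runif(n) < spec$frame_prob, 0L,
                    sample(1:2, n, replace = TRUE))
    off <- off + shift
  } else {
    off <- sample.int(L, n, replace = TRUE) - 1L
  }
  if (orf$strand == "+") {
    g5 <- orf$start + off
    s <- g5; e <- g5 + rl
  } else {
    g5 <- orf$end - 1L - off
    s <- g5 - rl + 1L; e <- g5 + 1L
  }
  s_wrapped <- s %% len
  data.frame(contig = orf$contig, start = s_wrapped, end = s_wrapped + rl,
             strand = orf$strand, read_length = rl, hit_count = 1L,
             stringsAsFactors = FALSE)
}

#' Simulate RIBO and RNA read libraries with planted truth
#'
#' Call after [simulate_genome()] on the same pseudo-random stream (do not
#' reseed in between; [simulate_dataset()] handles this). For each condition
#' and replicate, one RIBO and one RNA library are generated: RIBO reads are
#' placed within ORFs with 5'-end start enrichment and in-frame bias, RNA
#' reads uniformly along each ORF; per-ORF RIBO depth scales with the
#' planted TE at fixed RNA depth. An `rrna_fraction` of each library falls
#' in the rRNA locus and a `multimap_fraction` (of ORF + rRNA reads, drawn
#' among ORF reads) is tagged NH = 2.
#'
#' @param spec A `simulation_spec`.
#' @param sim Result of [simulate_genome()].
#' @return list: `reads_by_library` (named list of read data.frames),
#'   `sample_sheet` (data.frame without paths), `truth` (per-library planted
#'   counts plus per-condition TE vectors).
#' @export
simulate_reads <- function(spec, sim) {
  orfs <- sim$orfs
  len <- sim$genome$length
  conditions <- names(spec$te)
  libs <- list(); truth <- list(); sheet <- NULL
  for (cond in conditions) {
    for (method in c("RIBO", "RNA")) {
      for (rep_i in seq_len(spec$n_replicates)) {
        lib_id <- sprintf("%s_%s_r%d", cond, tolower(method), rep_i)
        per_orf <- if (method == "RIBO") {
          as.integer(round(spec$reads_per_orf * spec$te[[cond]]))
        } else {
          rep(spec$reads_per_orf, spec$n_orfs)
        }
        parts <- lapply(seq_len(spec$n_orfs), function(i) {
          place_orf_reads(spec, orfs[i, ], per_orf[i], method, len)
        })
        reads <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
        orf_of <- rep.int(seq_len(spec$n_orfs), per_orf)
        n_orf_reads <- nrow(reads)
        f <- spec$rrna_fraction
        n_rrna <- as.integer(round(n_orf_reads * f / (1 - f)))
        if (n_rrna > 0L) {
          rl <- draw_lengths(spec, n_rrna)
          s <- sim$regions$rrna[1L] +
            sample.int(diff(sim$regions$rrna) - max(rl), n_rrna, replace = TRUE) - 1L
          reads <- rbind(reads, data.frame(contig = "chr", start = s,
                                           end = s + rl, strand = "+",
                                           read_length = rl, hit_count = 1L,
                                           stringsAsFactors = FALSE))
        }
        n_mm <- as.integer(round(spec$multimap_fraction * (n_orf_reads + n_rrna)))
        mm_idx <- if (n_mm > 0L) sample.int(n_orf_reads, n_mm) else integer(0)
        reads$hit_count[mm_idx] <- 2L
        planted <- tabulate(orf_of, nbins = spec$n_orfs)
        retained_per_orf <- planted - tabulate(orf_of[mm_idx],
                                               nbins = spec$n_orfs)
        truth[[lib_id]] <- list(
          total_reads = n_orf_reads + n_rrna, rrna_reads = n_rrna,
          multimapped_reads = n_mm, background_reads = 0L,
          per_orf_planted = stats::setNames(as.integer(planted), orfs$orf_id),
          per_orf_retained = stats::setNames(as.integer(retained_per_orf),
                                             orfs$orf_id))
        libs[[lib_id]] <- reads
        sheet <- rbind(sheet, data.frame(library_id = lib_id, method = method,
                                         condition = cond, replicate = rep_i,
                                         path = paste0(lib_id, ".sam"),
                                         stringsAsFactors = FALSE))
      }
    }
  }
  if (spec$equalize_depth) {
    retained_core <- vapply(names(libs), function(id) {
      truth[[id]]$total_reads - truth[[id]]$rrna_reads -
        truth[[id]]$multimapped_reads
    }, integer(1))
    target <- max(retained_core)
    bg <- sim$regions$background
    for (id in names(libs)) {
      n_bg <- target - retained_core[[id]]
      if (n_bg > 0L) {
        rl <- draw_lengths(spec, n_bg)
        s <- bg[1L] + sample.int(diff(bg) - max(rl), n_bg, replace = TRUE) - 1L
        libs[[id]] <- rbind(libs[[id]],
                            data.frame(contig = "chr", start = s, end = s + rl,
                                       strand = "+", read_length = rl,
                                       hit_count = 1L, stringsAsFactors = FALSE))
      }
      truth[[id]]$background_reads <- as.integer(n_bg)
      truth[[id]]$total_reads <- truth[[id]]$total_reads + as.integer(n_bg)
    }
  }
  for (id in names(libs)) {
    libs[[id]]$qname <- sprintf("%s_read%06d", id, seq_len(nrow(libs[[id]])))
    rownames(libs[[id]]) <- NULL
  }
  truth$te <- spec$te
  list(reads_by_library = libs, sample_sheet = sheet, truth = truth)
}

#' Simulate predictor ORF calls
#'
#' Each (tool, condition, replicate) run detects every planted ORF
#' (annotated or novel) independently with probability `detect_prob` and
#' assigns a uniform score — a stand-in for REPARATION/DeepRibo-style output
#' consumed as GFF3.
#'
#' @param spec A `simulation_spec`.
#' @param sim Result of [simulate_genome()].
#' @param tools Predictor names.
#' @return list of prediction sets (`tool`, `condition`, `replicate`,
#'   `orfs`).
#' @export
simulate_predictions <- function(spec, sim,
                                 tools = c("reparation", "deepribo")) {
  out <- list()
  for (tool in tools) {
    for (cond in names(spec$te)) {
      for (rep_i in seq_len(spec$n_replicates)) {
        hit <- stats::runif(spec$n_orfs) < spec$detect_prob
        po <- sim$orfs[hit, names(sim$orfs) != "novel", drop = FALSE]
        if (nrow(po) > 0L) {
          po$score <- round(stats::runif(nrow(po), 0.5, 1), 4)
          po$source <- tool
          po$orf_id <- sprintf("%s_%s_r%d_%s", tool, cond, rep_i, po$orf_id)
          po$attributes <- paste0("ID=", po$orf_id)
        }
        out[[length(out) + 1L]] <- list(tool = tool, condition = cond,
                                        replicate = rep_i, orfs = po)
      }
    }
  }
  out
}

#' Write a complete synthetic dataset to disk
#'
#' Produces `genome.fasta`, `annotation.gff3`, one SAM per library,
#' predictor GFF3s under `predictions/`, `samples.tsv` and `truth.json`, all
#' deterministic under `spec$seed`.
#'
#' @param spec A `simulation_spec`.
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with the in-memory objects and file paths.
#' @export
simulate_dataset <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genome(spec)            # seeds the stream
  rd <- simulate_reads(spec, sim)
  preds <- simulate_predictions(spec, sim)
  genomes <- genome_set(list(sim$genome))
  write_fasta(genomes, file.path(out_dir, "genome.fasta"))
  write_gff3(sim$annotation, file.path(out_dir, "annotation.gff3"), genomes)
  for (id in names(rd$reads_by_library)) {
    write_sam(rd$reads_by_library[[id]], genomes,
              file.path(out_dir, paste0(id, ".sam")))
  }
  pred_dir <- file.path(out_dir, "predictions")
  dir.create(pred_dir, showWarnings = FALSE)
  pred_files <- list()
  for (ps in preds) {
    f <- file.path(pred_dir, sprintf("%s_%s_r%d.gff3", ps$tool, ps$condition,
                                     ps$replicate))
    write_gff3(ps$orfs, f, genomes)
    pred_files[[length(pred_files) + 1L]] <-
      list(tool = ps$tool, condition = ps$condition,
           replicate = ps$replicate, file = f)
  }
  utils::write.table(rd$sample_sheet, file.path(out_dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(rd$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(spec = spec, sim = sim, reads = rd, predictions = preds,
                 prediction_files = pred_files, dir = out_dir))
}
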