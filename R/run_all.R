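# End-to-end pipeline: filter -> coverage -> metagene -> merge -> quantify ->
# report, executed sequentially in-process from one validated configuration.
# Deterministic: the pipeline itself draws no random numbers, so identical
# inputs give byte-identical tabular and track outputs.

#' Build a run configuration
#'
#' @param genome Path to genome FASTA.
#' @param annotation Path to annotation GFF3.
#' @param sample_sheet Path to the sample-sheet TSV.
#' @param predictions list of lists with `tool`, `condition`, `replicate`,
#'   `file` (predictor GFF3 path).
#' @param de_tables list of lists with `contrast`, `file` (TSV path);
#'   optional.
#' @param out_dir Output directory.
#' @param circular Circularity passed to [read_fasta()] (NULL = header
#'   token).
#' @param rrna_types Annotation feature types filtered as contaminants.
#' @param coverage_modes,coverage_norms Coverage track variants to write.
#' @param window_upstream,window_downstream,read_lengths,anchor Metagene
#'   parameters.
#' @param seed Recorded in the manifest (the pipeline is deterministic; the
#'   seed matters only to upstream simulation).
#' @return list of class `run_config`.
#' @export
run_config <- function(genome, annotation, sample_sheet, predictions = list(),
                       de_tables = list(), out_dir,
                       circular = NULL, rrna_types = "rRNA",
                       coverage_modes = c("full", "fiveprime", "threeprime",
                                          "center"),
                       coverage_norms = c("raw", "cpm"),
                       window_upstream = 50L, window_downstream = 50L,
                       read_lengths = 20:45, anchor = "fiveprime",
                       seed = 1L) {
  structure(list(genome = genome, annotation = annotation,
                 sample_sheet = sample_sheet, predictions = predictions,
                 de_tables = de_tables, out_dir = out_dir,
                 circular = circular, rrna_types = rrna_types,
                 coverage_modes = coverage_modes,
                 coverage_norms = coverage_norms,
                 window_upstream = as.integer(window_upstream),
                 window_downstream = as.integer(window_downstream),
                 read_lengths = read_lengths, anchor = anchor,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from a JSON file
#'
#' Relative paths are resolved against the config file's directory.
#'
#' @param path JSON file whose keys mirror [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (grepl("^/", p)) p else file.path(base, p)
  for (k in c("genome", "annotation", "sample_sheet", "out_dir")) {
    if (!is.null(cfg[[k]])) cfg[[k]] <- resolve(cfg[[k]])
  }
  cfg$predictions <- lapply(cfg$predictions, function(p) {
    p$file <- resolve(p$file); p
  })
  cfg$de_tables <- lapply(cfg$de_tables, function(p) {
    p$file <- resolve(p$file); p
  })
  do.call(run_config, cfg)
}

#' Validate a run configuration
#'
#' Checks file existence, parameter ranges and that every condition with a
#' RIBO library also has an RNA library — before any computation.
#'
#' @param config A `run_config`.
#' @return The config, invisibly; errors on violations.
#' @export
validate_config <- function(config) {
  for (k in c("genome", "annotation", "sample_sheet")) {
    if (!file.exists(config[[k]])) {
      stop("config: ", k, " file does not exist: ", config[[k]])
    }
  }
  for (p in config$predictions) {
    if (!file.exists(p$file)) stop("config: prediction file missing: ", p$file)
  }
  for (p in config$de_tables) {
    if (!file.exists(p$file)) stop("config: DE table missing: ", p$file)
  }
  stopifnot(config$window_upstream > 0L, config$window_downstream > 0L,
            all(config$coverage_modes %in%
                  c("full", "fiveprime", "threeprime", "center")),
            all(config$coverage_norms %in% c("raw", "cpm")),
            config$anchor %in% c("fiveprime", "threeprime", "center"))
  sheet <- read_sample_sheet(config$sample_sheet)
  for (cond in unique(sheet$condition)) {
    has_ribo <- any(sheet$condition == cond & sheet$method == "RIBO")
    has_rna <- any(sheet$condition == cond & sheet$method == "RNA")
    if (has_ribo && !has_rna) {
      stop("config validation: condition '", cond,
           "' has RIBO libraries but no RNA library")
    }
  }
  invisible(config)
}

log_stage <- function(stage, t0) {
  message(sprintf("[riboloop] %-10s %6.2fs", stage,
                  as.numeric(Sys.time()) - t0))
}

#' Run the whole pipeline
#'
#' Executes filter, coverage, metagene, merge, quantify and report in order
#' and writes every output exactly once under `config$out_dir`, plus a
#' machine-readable `manifest.json` (inputs, parameters, package version,
#' md5 checksums of all outputs). Any stage error aborts with the stage
#' name.
#'
#' @param config A `run_config`.
#' @return The output directory, invisibly.
#' @export
run_all <- function(config) {
  validate_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- "load"
  t0 <- as.numeric(Sys.time())
  result <- tryCatch({
    genomes <- read_fasta(config$genome, circular = config$circular)
    annotation <- read_gff3(config$annotation, genomes)
    sheet <- read_sample_sheet(config$sample_sheet)
    log_stage(stage, t0)

    stage <- "filter"
    reads_by_library <- list()
    reports <- NULL
    for (i in seq_len(nrow(sheet))) {
      reads <- read_alignments(sheet$path[i], genomes)
      fl <- filter_reads(reads, annotation, genomes,
                         rrna_types = config$rrna_types)
      reads_by_library[[sheet$library_id[i]]] <- fl$reads
      reports <- rbind(reports,
                       cbind(library_id = sheet$library_id[i], fl$report))
    }
    utils::write.table(reports, file.path(out, "filter_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage(stage, t0)

    stage <- "coverage"
    cov_dir <- file.path(out, "coverage")
    for (id in names(reads_by_library)) {
      write_coverage_tracks(reads_by_library[[id]], genomes, cov_dir, id,
                            modes = config$coverage_modes,
                            normalizations = config$coverage_norms)
    }
    log_stage(stage, t0)

    stage <- "metagene"
    mg_dir <- file.path(out, "metagene")
    dir.create(mg_dir, showWarnings = FALSE)
    sp <- collect_start_positions(annotation, genomes,
                                  config$window_upstream,
                                  config$window_downstream)
    ribo_ids <- sheet$library_id[sheet$method == "RIBO"]
    for (id in ribo_ids) {
      prof <- metagene_profile(reads_by_library[[id]], sp$starts, genomes,
                               config$window_upstream,
                               config$window_downstream,
                               config$read_lengths, config$anchor)
      write_metagene(prof, file.path(mg_dir, paste0(id, ".metagene.tsv")))
      write_frame_summary(frame_summary(prof),
                          file.path(mg_dir, paste0(id, ".frame_summary.tsv")))
    }
    log_stage(stage, t0)

    stage <- "merge"
    prediction_sets <- lapply(config$predictions, function(p) {
      list(tool = p$tool, condition = p$condition, replicate = p$replicate,
           orfs = read_gff3(p$file, genomes))
    })
    merged <- merge_predictions(annotation, prediction_sets, genomes)
    merged <- annotate_features(merged, genomes)
    write_merged_gff3(merged, file.path(out, "merged_orfs.gff3"), genomes)
    log_stage(stage, t0)

    stage <- "quantify"
    quant <- quantify_orfs(merged, reads_by_library, sheet, genomes)
    utils::write.table(
      data.frame(orf_id = rownames(quant$counts), quant$counts,
                 check.names = FALSE),
      file.path(out, "counts.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    te_df <- data.frame(orf_id = rownames(quant$te),
                        signif(quant$te, 6), check.names = FALSE)
    utils::write.table(te_df, file.path(out, "te.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
    log_stage(stage, t0)

    stage <- "report"
    de_tables <- lapply(config$de_tables, function(p) {
      list(contrast = p$contrast, table = read_de_table(p$file))
    })
    de <- join_differential(merged, de_tables, genomes)
    overview <- build_overview(merged, quant, de, genomes)
    write_overview(overview, file.path(out, "overview.tsv"))
    diagnostics <- quant$diagnostics
    diagnostics$excluded_genes <- sp$excluded
    diagnostics$unmatched_de_rows <- nrow(de$unmatched)
    utils::write.table(diagnostics, file.path(out, "diagnostics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage(stage, t0)
    TRUE
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package = "riboloop",
    version = as.character(utils::packageVersion("riboloop")),
    created = format(Sys.time(), tz = "UTC"),
    inputs = list(genome = config$genome, annotation = config$annotation,
                  sample_sheet = config$sample_sheet),
    parameters = config[c("rrna_types", "coverage_modes", "coverage_norms",
                          "window_upstream", "window_downstream",
                          "read_lengths", "anchor", "seed")],
    outputs = lapply(stats::setNames(files, substring(files, nchar(out) + 2L)),
                     function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}
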