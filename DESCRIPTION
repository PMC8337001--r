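Package: riboloop
Title: Bacterial Ribosome Profiling Post-Processing with Circular Genome Support
Version: 0.1.0
Authors@R: person("riboloop", "developers", role = c("aut", "cre"),
    email = "riboloop@example.org")
Description: Tools for the downstream analysis of bacterial ribosome profiling
    (Ribo-seq) experiments starting from mapped reads: removal of multimapped
    and rRNA-derived reads, strand-specific per-nucleotide coverage tracks in
    full-read and single-nucleotide (5', 3', center) mapping modes, metagene
    profiling of ribosome density around start codons stratified by read
    length, merging of ORF predictions from external predictors with the
    reference annotation into a non-redundant list with novelty calls,
    read counting with RPKM/TPM normalisation and per-condition translation
    efficiency, and a single enriched per-ORF overview table. All coordinate
    arithmetic supports circular bacterial chromosomes, including
    origin-spanning genes and reads. A self-contained simulator generates
    genomes, annotations, predictor outputs and SAM read libraries with
    planted truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
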