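#' Validated pipeline configuration
#'
#' Collects every input and threshold of a full run; unknown keys are
#' rejected and files are checked before any stage runs.
#'
#' @param fastq Named list/vector of FASTQ paths (names = tissue labels), or
#'   `NULL` when `reads` are passed to [run_pipeline()] directly.
#' @param genome_fasta Path to the genome FASTA (or `NULL`).
#' @param mature_fasta Path to the miRBase-style mature reference FASTA.
#' @param transcript_fasta Optional transcript FASTA for target scanning.
#' @param ct_table Optional Ct table path.
#' @param adapter3 3' adapter sequence.
#' @param min_len,max_len Read retention window.
#' @param params A [discovery_params()] list.
#' @param species_code Naming prefix.
#' @param out_dir Optional output directory for stage artifacts.
#' @param ... Unknown keys raise an error.
#' @return A validated list of class `mulmir_config`.
#' @export
pipeline_config <- function(fastq = NULL, genome_fasta = NULL,
                            mature_fasta = NULL, transcript_fasta = NULL,
                            ct_table = NULL, adapter3 = default_adapter(),
                            min_len = 18, max_len = 30,
                            params = discovery_params(),
                            species_code = "mno", out_dir = NULL, ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    stop("unknown configuration keys: ",
         paste(names(extra), collapse = ", "), call. = FALSE)
  }
  cfg <- list(fastq = fastq, genome_fasta = genome_fasta,
              mature_fasta = mature_fasta,
              transcript_fasta = transcript_fasta, ct_table = ct_table,
              adapter3 = adapter3, min_len = min_len, max_len = max_len,
              params = params, species_code = species_code,
              out_dir = out_dir)
  for (p in c("genome_fasta", "mature_fasta", "transcript_fasta",
              "ct_table")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stop("configured file does not exist: ", p, " = ", cfg[[p]],
           call. = FALSE)
    }
  }
  for (f in cfg$fastq) {
    if (!file.exists(f)) stop("FASTQ not found: ", f, call. = FALSE)
  }
  structure(cfg, class = c("mulmir_config", "list"))
}

#' Run the full discovery pipeline
#'
#' Stages, in order: read cleaning and collapsing per tissue; annotation
#' cascade; conserved-miRNA cataloguing; novel miRNA discovery on
#' unannotated reads; RPM normalisation and family-level tissue-bias calls;
#' optional target scanning of the catalog miRNAs. Each stage's artifact is
#' returned (and written as TSV when `out_dir` is configured); the report
#' aggregates per-category read counts and catalog sizes.
#'
#' @param config A [pipeline_config()].
#' @param reads Optional named list of raw-read tibbles (`seq`, `qual`),
#'   overriding `config$fastq` (used with the simulator).
#' @param annotation_refs Optional `mulmir_annotation_db` with the
#'   non-coding/genic reference sets.
#' @return List of class `mulmir_run`: `libraries`, `annotations`,
#'   `conserved`, `novel`, `expression`, `bias`, `targets`, `report`.
#' @export
run_pipeline <- function(config, reads = NULL, annotation_refs = NULL) {
  stopifnot(inherits(config, "mulmir_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (is.null(reads)) {
    if (is.null(config$fastq)) {
      stop("no reads: configure 'fastq' or pass 'reads'", call. = FALSE)
    }
    reads <- stage("read", lapply(config$fastq, read_fastq))
  }
  libs <- stage("preprocess", purrr::imap(reads, function(r, label) {
    clean_reads(r, adapter3 = config$adapter3, min_len = config$min_len,
                max_len = config$max_len, label = label)
  }))
  mature_ref <- NULL
  if (!is.null(config$mature_fasta)) {
    mature_ref <- stage("reference", read_mature_reference(config$mature_fasta))
  }
  genome <- NULL
  if (!is.null(config$genome_fasta)) {
    genome <- stage("genome", read_fasta(config$genome_fasta))
  }
  db <- annotation_refs %||% annotation_db()
  if (!is.null(genome)) db$genome <- genome
  anns <- stage("annotate", lapply(libs, classify, db = db,
                                   mature_ref = mature_ref))
  conserved <- NULL
  if (!is.null(mature_ref)) {
    conserved <- stage("conserved",
                       identify_conserved(libs, mature_ref,
                                          species_code = config$species_code))
  }
  novel <- NULL
  if (!is.null(genome)) {
    unann <- unique(unlist(lapply(anns, function(a) {
      a$seq[a$category == "unannotated"]
    })))
    novel <- stage("novel", discover_novel(libs, genome, config$params,
                                           candidate_seqs = unann))
  }
  expression <- NULL
  bias <- NULL
  if (!is.null(conserved) && nrow(conserved) > 0) {
    totals <- vapply(libs, total_clean, numeric(1))
    fam <- family_aggregate(conserved)
    expression <- stage("expression", to_rpm(fam, totals))
    bias <- stage("bias", call_bias(expression))
  }
  targets <- NULL
  if (!is.null(config$transcript_fasta) && !is.null(conserved)) {
    tx <- stage("transcripts", read_fasta(config$transcript_fasta))
    targets <- stage("targets",
                     scan_targets(stats::setNames(conserved$seq,
                                                  conserved$name), tx))
  }
  report <- bind_rows(lapply(anns, glance))
  out <- list(libraries = libs, annotations = anns, conserved = conserved,
              novel = novel, expression = expression, bias = bias,
              targets = targets, report = report, config = config)
  class(out) <- "mulmir_run"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    # audit log: every threshold the run used
    p <- config$params
    writeLines(c(
      paste0("adapter3=", config$adapter3),
      paste0("min_len=", config$min_len),
      paste0("max_len=", config$max_len),
      vapply(names(p), function(k) {
        paste0(k, "=", paste(p[[k]], collapse = ","))
      }, character(1))),
      file.path(config$out_dir, "run_parameters.txt"))
    readr::write_tsv(report, file.path(config$out_dir, "report.tsv"))
    if (!is.null(conserved)) {
      readr::write_tsv(as_tibble(conserved),
                       file.path(config$out_dir, "conserved_catalog.tsv"))
    }
    if (!is.null(novel) && nrow(novel$catalog) > 0) {
      readr::write_tsv(select(as_tibble(novel$catalog), -"loci"),
                       file.path(config$out_dir, "novel_catalog.tsv"))
      loci <- bind_rows(novel$catalog$loci) %>%
        mutate(id = rep(novel$catalog$name,
                        vapply(novel$catalog$loci, nrow, integer(1))))
      write_loci_gff(loci, file.path(config$out_dir, "novel_loci.gff3"))
    }
    if (!is.null(bias)) {
      readr::write_tsv(as_tibble(bias),
                       file.path(config$out_dir, "bias_calls.tsv"))
    }
    if (!is.null(targets)) {
      readr::write_tsv(targets, file.path(config$out_dir, "targets.tsv"))
    }
  }
  out
}

#' @export
print.mulmir_run <- function(x, ...) {
  cat("mulmir pipeline run\n")
  cat("  libraries: ", paste(names(x$libraries), collapse = ", "), "\n")
  if (!is.null(x$conserved)) {
    cat("  conserved miRNAs:", nrow(x$conserved), "\n")
  }
  if (!is.null(x$novel)) cat("  novel miRNAs:", nrow(x$novel$catalog), "\n")
  if (!is.null(x$bias)) {
    cat("  biased families:", sum(x$bias$label != "unbiased"), "\n")
  }
  invisible(x)
}
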