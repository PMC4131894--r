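.as_seqvec <- function(x) {
  if (is.null(x)) return(character(0))
  if (is.data.frame(x)) x <- x$seq
  x <- normalize_alphabet(x)
  stopifnot(all(nzchar(x)))
  x
}

#' Bundle annotation reference sets
#'
#' Holds the user-supplied reference sequence sets used by the annotation
#' cascade and (optionally) the genome. Each set may be a character vector of
#' sequences or a tibble with a `seq` column (e.g. from [read_fasta()]).
#'
#' @param rRNA,tRNA,snRNA,snoRNA Non-coding RNA reference sets.
#' @param repeats Repeat-sequence set.
#' @param exon,intron Exonic and intronic sequence sets, given in
#'   transcription orientation (a read matching the reverse complement is
#'   classed antisense).
#' @param genome Genome as a tibble with columns `id`, `seq`, or `NULL`.
#' @return An object of class `mulmir_annotation_db`.
#' @export
annotation_db <- function(rRNA = NULL, tRNA = NULL, snRNA = NULL,
                          snoRNA = NULL, repeats = NULL, exon = NULL,
                          intron = NULL, genome = NULL) {
  db <- list(rRNA = .as_seqvec(rRNA), tRNA = .as_seqvec(tRNA),
             snRNA = .as_seqvec(snRNA), snoRNA = .as_seqvec(snoRNA),
             repeat_ = .as_seqvec(repeats), exon = .as_seqvec(exon),
             intron = .as_seqvec(intron), genome = genome)
  if (!is.null(genome)) stopifnot(all(c("id", "seq") %in% names(genome)))
  structure(db, class = "mulmir_annotation_db")
}

# One haystack string per reference set; reads never contain N so a triple-N
# separator cannot produce spurious cross-boundary hits.
.haystack <- function(seqs, both_strands = TRUE) {
  if (length(seqs) == 0) return(NULL)
  if (both_strands) seqs <- c(seqs, revcomp(seqs))
  paste(seqs, collapse = "NNN")
}

.detect_in <- function(reads, haystack) {
  if (is.null(haystack) || length(reads) == 0) {
    return(rep(FALSE, length(reads)))
  }
  subj <- Biostrings::DNAString(haystack)
  out <- logical(length(reads))
  for (w in unique(nchar(reads))) {
    idx <- which(nchar(reads) == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(reads[idx]))
    out[idx] <- Biostrings::countPDict(pd, subj) > 0
  }
  out
}

#' Map reads to exact genomic loci
#'
#' Full-length, ungapped, exact matches on both strands; reverse-strand
#' matches are located via the reverse complement. Coordinates are 1-based
#' inclusive.
#'
#' @param lib A `mulmir_library` or a character vector of read sequences.
#' @param genome Tibble with columns `id`, `seq` (e.g. from [read_fasta()]).
#' @return Tibble with columns `seq`, `chrom`, `start`, `end`, `strand`
#'   (zero rows for reads with no match).
#' @export
match_genome <- function(lib, genome) {
  reads <- if (is.character(lib)) unique(lib) else unique(lib$seq)
  stopifnot(all(c("id", "seq") %in% names(genome)))
  empty <- tibble(seq = character(), chrom = character(), start = integer(),
                  end = integer(), strand = character())
  if (length(reads) == 0) return(empty)
  contigs <- lapply(normalize_alphabet(genome$seq), Biostrings::DNAString)
  names(contigs) <- genome$id
  # constant-width preprocessed dictionaries, one per read length
  scan_patterns <- function(pats, orig, strand) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(pats))
    rows <- list()
    for (ci in seq_along(contigs)) {
      m <- Biostrings::matchPDict(pd, contigs[[ci]])
      n_per <- lengths(m)
      if (sum(n_per) == 0) next
      ir <- unlist(m, use.names = FALSE)
      rows[[length(rows) + 1]] <- tibble(
        seq = rep(orig, n_per),
        chrom = names(contigs)[ci],
        start = BiocGenerics::start(ir), end = BiocGenerics::end(ir),
        strand = strand)
    }
    rows
  }
  out <- list()
  for (w in unique(nchar(reads))) {
    grp <- reads[nchar(reads) == w]
    out <- c(out, scan_patterns(grp, grp, "+"),
             scan_patterns(revcomp(grp), grp, "-"))
  }
  out <- bind_rows(out)
  if (nrow(out) == 0) return(empty)
  arrange(out, .data$chrom, .data$start, .data$seq)
}

.CASCADE <- c("rRNA", "tRNA", "snRNA", "snoRNA", "miRNA", "repeat",
              "exon_sense", "exon_antisense", "intron_sense",
              "intron_antisense", "unannotated")

#' Classify library reads into annotation categories
#'
#' A priority cascade assigns each unique read exactly one category, first
#' hit wins: rRNA, tRNA, snRNA, snoRNA (exact substring of a reference
#' sequence, either orientation), then miRNA (exact full-length match to a
#' mature reference), then repeat, then exon and intron split into sense
#' (substring in transcription orientation) and antisense (substring of the
#' reverse complement), else unannotated. miRNA is deliberately checked
#' before repeat/exon/intron so miRNAs inside annotated features are not
#' lost; the non-coding RNA sets still pre-empt it, mirroring an
#' Rfam-before-miRBase workflow.
#'
#' @param lib A `mulmir_library`.
#' @param db A `mulmir_annotation_db`.
#' @param mature_ref Mature miRNA reference: tibble with a `seq` column (e.g.
#'   from [read_mature_reference()]) or a character vector.
#' @return A `mulmir_annotation`: the library tibble with an added
#'   `category` column plus a `matches_genome` logical column when the db
#'   carries a genome. Summaries via [tidy()][generics::tidy] /
#'   [glance()][generics::glance].
#' @export
classify <- function(lib, db, mature_ref = NULL) {
  stopifnot(inherits(lib, "mulmir_library"),
            inherits(db, "mulmir_annotation_db"))
  reads <- lib$seq
  n <- length(reads)
  cat_lab <- rep(NA_character_, n)
  assign_cat <- function(hit, label) {
    sel <- is.na(cat_lab) & hit
    cat_lab[sel] <<- label
  }
  for (nc in c("rRNA", "tRNA", "snRNA", "snoRNA")) {
    assign_cat(.detect_in(reads, .haystack(db[[nc]])), nc)
  }
  matures <- if (is.null(mature_ref)) character(0) else .as_seqvec(mature_ref)
  assign_cat(reads %in% matures, "miRNA")
  assign_cat(.detect_in(reads, .haystack(db$repeat_)), "repeat")
  hs_exon_s <- .haystack(db$exon, both_strands = FALSE)
  hs_exon_a <- .haystack(revcomp(db$exon), both_strands = FALSE)
  hs_intr_s <- .haystack(db$intron, both_strands = FALSE)
  hs_intr_a <- .haystack(revcomp(db$intron), both_strands = FALSE)
  assign_cat(.detect_in(reads, hs_exon_s), "exon_sense")
  assign_cat(.detect_in(reads, hs_exon_a), "exon_antisense")
  assign_cat(.detect_in(reads, hs_intr_s), "intron_sense")
  assign_cat(.detect_in(reads, hs_intr_a), "intron_antisense")
  cat_lab[is.na(cat_lab)] <- "unannotated"

  out <- lib %>% mutate(category = factor(cat_lab, levels = .CASCADE))
  if (!is.null(db$genome)) {
    hs_gen <- .haystack(normalize_alphabet(db$genome$seq))
    out$matches_genome <- .detect_in(reads, hs_gen)
  }
  structure(out, label = library_label(lib), total_raw = total_raw(lib),
            total_clean = total_clean(lib),
            class = c("mulmir_annotation", "tbl_df", "tbl", "data.frame"))
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' Per-category read counts of an annotation result
#'
#' @param x A `mulmir_annotation`.
#' @param ... Unused.
#' @return Tibble with columns `category`, `unique_reads`, `total_reads`
#'   (all cascade categories present, zero-filled).
#' @export
tidy.mulmir_annotation <- function(x, ...) {
  tbl <- as_tibble(x) %>%
    group_by(.data$category, .drop = FALSE) %>%
    summarise(unique_reads = dplyr::n(), total_reads = sum(.data$count),
              .groups = "drop") %>%
    mutate(category = as.character(.data$category))
  tbl$total_reads[is.na(tbl$total_reads)] <- 0L
  tbl
}

#' One-row summary of an annotation result
#'
#' @param x A `mulmir_annotation`.
#' @param ... Unused.
#' @return One-row tibble: library label, raw/clean totals, genome-matching
#'   totals (when available) and the miRNA / unannotated totals.
#' @export
glance.mulmir_annotation <- function(x, ...) {
  td <- tidy(x)
  pick <- function(cat) td$total_reads[td$category == cat]
  tibble(
    label = attr(x, "label"),
    total_raw = attr(x, "total_raw"),
    total_clean = attr(x, "total_clean"),
    unique_clean = nrow(x),
    match_genome_unique = if ("matches_genome" %in% names(x))
      sum(x$matches_genome) else NA_integer_,
    match_genome_total = if ("matches_genome" %in% names(x))
      sum(x$count[x$matches_genome]) else NA_integer_,
    miRNA_total = pick("miRNA"),
    unannotated_total = pick("unannotated"))
}
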