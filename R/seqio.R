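#' @useDynLib mulmir, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import tibble
#' @importFrom dplyr %>% mutate filter arrange group_by summarise ungroup
#'   select across left_join bind_rows bind_cols desc n row_number rename
#'   distinct pull
#' @importFrom rlang .data
NULL

BASES <- c("A", "C", "G", "T", "U", "N")

#' Normalise a sequence to a single internal alphabet
#'
#' All pipeline sequences are held internally as uppercase DNA (U converted to
#' T); conversion back to U happens only at display or folding boundaries.
#' The operation is idempotent.
#'
#' @param seq Character vector of sequences.
#' @param alphabet `"DNA"` (default) maps U to T; `"RNA"` maps T to U.
#' @return Character vector of normalised sequences.
#' @export
normalize_alphabet <- function(seq, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  seq <- toupper(seq)
  bad <- grepl("[^ACGTUN]", seq)
  if (any(bad)) {
    stop("sequence contains characters outside {A,C,G,T,U,N}: ",
         seq[which(bad)[1]], call. = FALSE)
  }
  if (alphabet == "DNA") chartr("U", "T", seq) else chartr("T", "U", seq)
}

#' Reverse complement (DNA alphabet)
#'
#' @param seq Character vector of DNA sequences (may contain N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  if (length(seq) == 0) return(character(0))
  unname(as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(seq))))
}

#' Read a FASTA file into a tibble
#'
#' One row per record; sequences are uppercased and alphabet-normalised.
#'
#' @param path Path to a FASTA file.
#' @param alphabet Internal alphabet, `"DNA"` (default) or `"RNA"`.
#' @return A tibble with columns `id`, `description`, `seq`. An empty file
#'   yields a zero-row tibble.
#' @export
read_fasta <- function(path, alphabet = "DNA") {
  stopifnot(file.exists(path))
  if (file.size(path) == 0) {
    return(tibble(id = character(), description = character(), seq = character()))
  }
  first <- readLines(path, n = 50L, warn = FALSE)
  nonblank <- which(nzchar(trimws(first)))
  if (length(nonblank) > 0 && !startsWith(trimws(first[nonblank[1]]), ">")) {
    stop("malformed FASTA header at line ", nonblank[1], " of ", path,
         call. = FALSE)
  }
  if (length(nonblank) == 0) {
    return(tibble(id = character(), description = character(), seq = character()))
  }
  x <- Biostrings::readBStringSet(path, format = "fasta")
  if (any(Biostrings::width(x) == 0)) {
    bad <- names(x)[Biostrings::width(x) == 0][1]
    stop("record '", bad, "' in ", path, " has an empty sequence", call. = FALSE)
  }
  full <- names(x)
  id <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  tibble(id = id, description = desc,
         seq = unname(normalize_alphabet(as.character(x), alphabet)))
}

#' Write a tibble of sequences to FASTA
#'
#' @param df Tibble with columns `id` and `seq` (optional `description`).
#' @param path Output path.
#' @param width Line-wrap width (default 70 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(df, path, width = 70) {
  stopifnot(all(c("id", "seq") %in% names(df)))
  hdr <- df$id
  if ("description" %in% names(df)) {
    hdr <- ifelse(nzchar(df$description), paste(df$id, df$description), df$id)
  }
  lines <- character(0)
  for (i in seq_len(nrow(df))) {
    s <- df$seq[i]
    starts <- seq(1, nchar(s), by = width)
    lines <- c(lines, paste0(">", hdr[i]),
               substring(s, starts, pmin(starts + width - 1, nchar(s))))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a 4-line FASTQ file into a tibble
#'
#' @param path Path to a FASTQ file.
#' @return A tibble with columns `id`, `seq`, `qual`. Sequence and quality
#'   lengths are checked per record.
#' @export
read_fastq <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0) {
    return(tibble(id = character(), seq = character(), qual = character()))
  }
  x <- tryCatch(
    Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stop("FASTQ parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  qual <- as.character(S4Vectors::mcols(x)$qualities)
  seqs <- as.character(x)
  bad <- nchar(seqs) != nchar(qual)
  if (any(bad)) {
    stop("FASTQ record '", names(x)[which(bad)[1]],
         "': sequence and quality lengths differ", call. = FALSE)
  }
  tibble(id = sub("\\s.*$", "", names(x)),
         seq = unname(normalize_alphabet(seqs)), qual = unname(qual))
}

#' Parse a miRNA family label from a miRBase-style name
#'
#' `"gma-miR156f"`, `"zma-miR156g-3p"` and `"mtr-miR4414a-5p"` all parse to
#' the family given by "miR" plus the leading integer of the token after
#' "miR"; letter variants and arm suffixes are stripped.
#'
#' @param name Character vector of miRNA names.
#' @return Character vector of family labels such as `"miR156"`.
#' @export
parse_family_label <- function(name) {
  m <- regmatches(name, regexpr("miR[0-9]+", name))
  ok <- grepl("miR[0-9]+", name)
  if (any(!ok)) {
    stop("no miR family token in name '", name[which(!ok)[1]], "'",
         call. = FALSE)
  }
  m
}

#' Read a miRBase-style mature miRNA reference FASTA
#'
#' Record names are expected to look like `"gma-miR156f"` or
#' `"osa-miR166g-3p"`: the species code is the text before the first `-`
#' (names without a `-` get species `"unknown"` with a warning), and the
#' family label is parsed with [parse_family_label()] (`NA` with a warning if
#' no miR token is present).
#'
#' @param path Path to the mature-reference FASTA.
#' @return A tibble with columns `name`, `species`, `family`, `arm`, `seq`
#'   (DNA alphabet).
#' @export
read_mature_reference <- function(path) {
  df <- read_fasta(path, alphabet = "DNA")
  if (nrow(df) == 0) {
    return(tibble(name = character(), species = character(),
                  family = character(), arm = character(), seq = character()))
  }
  has_dash <- grepl("-", df$id, fixed = TRUE)
  if (any(!has_dash)) {
    warning(sum(!has_dash), " reference name(s) without '-': species set to ",
            "'unknown' (first: '", df$id[which(!has_dash)[1]], "')",
            call. = FALSE)
  }
  species <- ifelse(has_dash, sub("-.*$", "", df$id), "unknown")
  has_fam <- grepl("miR[0-9]+", df$id)
  if (any(!has_fam)) {
    warning(sum(!has_fam), " reference name(s) without a miR family token; ",
            "family set to NA", call. = FALSE)
  }
  family <- rep(NA_character_, nrow(df))
  family[has_fam] <- parse_family_label(df$id[has_fam])
  arm <- ifelse(grepl("-(3p|5p)$", df$id), sub("^.*-(3p|5p)$", "\\1", df$id),
                NA_character_)
  tibble(name = df$id, species = species, family = family, arm = arm,
         seq = df$seq)
}

#' Write genomic loci to a GFF3 file
#'
#' Coordinates are 1-based inclusive; strand `"."` is emitted verbatim.
#'
#' @param loci Tibble with columns `chrom`, `start`, `end`, `strand`, `id`
#'   (further columns become GFF3 attributes).
#' @param path Output path.
#' @param type Feature type for column 3 (default `"miRNA_primary_transcript"`).
#' @param source Source label for column 2.
#' @return `path`, invisibly.
#' @export
write_loci_gff <- function(loci, path, type = "miRNA_primary_transcript",
                           source = "mulmir") {
  need <- c("chrom", "start", "end", "strand", "id")
  stopifnot(all(need %in% names(loci)))
  if (nrow(loci) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  if (any(loci$start > loci$end)) {
    stop("locus with start > end: ",
         loci$id[which(loci$start > loci$end)[1]], call. = FALSE)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start, end = loci$end),
    strand = ifelse(loci$strand == ".", "*", loci$strand))
  S4Vectors::mcols(gr)$ID <- loci$id
  S4Vectors::mcols(gr)$type <- type
  S4Vectors::mcols(gr)$source <- source
  extra <- setdiff(names(loci), c(need, "type", "source"))
  for (col in extra) S4Vectors::mcols(gr)[[col]] <- loci[[col]]
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Read a GFF3 file of loci back into a tibble
#'
#' Inverse of [write_loci_gff()] for round-tripping.
#'
#' @param path Path to a GFF3 file.
#' @return Tibble with columns `chrom`, `start`, `end`, `strand`, `id`.
#' @export
read_loci_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), id = character()))
  }
  strand <- as.character(BiocGenerics::strand(gr))
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
         strand = ifelse(strand == "*", ".", strand),
         id = as.character(S4Vectors::mcols(gr)$ID))
}

#' Read a qRT-PCR Ct table
#'
#' Expects a UTF-8 tab-separated file with a header row and columns `assay`,
#' `sample`, `replicate`, `ct`.
#'
#' @param path Path to the delimited text file.
#' @return Tibble with columns `assay`, `sample`, `replicate` (integer) and
#'   `ct` (double), checked for finite Ct values and unique keys.
#' @export
read_ct_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("assay", "sample", "replicate", "ct")
  if (!all(need %in% names(df))) {
    stop("Ct table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ct <- suppressWarnings(as.numeric(df$ct))
  bad <- !is.finite(ct)
  if (any(bad)) {
    stop("non-numeric or missing Ct in row ", which(bad)[1], " (assay '",
         df$assay[which(bad)[1]], "')", call. = FALSE)
  }
  out <- tibble(assay = df$assay, sample = df$sample,
                replicate = as.integer(df$replicate), ct = ct)
  key <- paste(out$assay, out$sample, out$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    d <- out[duplicated(key), ][1, ]
    stop("duplicated (assay, sample, replicate) key: ", d$assay, "/",
         d$sample, "/", d$replicate, call. = FALSE)
  }
  out
}
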