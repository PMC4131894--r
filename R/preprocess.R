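#' Construct a collapsed read library
#'
#' @param tbl Tibble with columns `seq` and `count`.
#' @param label Tissue label.
#' @param total_raw Number of raw reads the library was built from.
#' @return A `mulmir_library`: the tibble with attributes `label`,
#'   `total_raw` and `total_clean` (= sum of counts).
#' @export
new_read_library <- function(tbl, label = "library", total_raw = sum(tbl$count)) {
  stopifnot(all(c("seq", "count") %in% names(tbl)), all(tbl$count >= 0))
  tbl <- as_tibble(tbl[, c("seq", "count")])
  structure(tbl, label = label, total_raw = as.integer(total_raw),
            total_clean = as.integer(sum(tbl$count)),
            class = c("mulmir_library", class(tbl)))
}

#' @rdname new_read_library
#' @param lib A `mulmir_library`.
#' @export
library_label <- function(lib) attr(lib, "label")

#' @rdname new_read_library
#' @export
total_clean <- function(lib) attr(lib, "total_clean")

#' @rdname new_read_library
#' @export
total_raw <- function(lib) attr(lib, "total_raw")

# Locate the 3' adapter in a read: leftmost start p such that the read suffix
# from p matches a prefix of the adapter with at most `max_mismatch`
# mismatches and an overlap of at least `min_overlap` nt. Returns p (trim
# point) or NA. Works on one sequence.
.find_adapter <- function(read, adapter, min_overlap = 6, max_mismatch = 1) {
  L <- nchar(read)
  A <- nchar(adapter)
  rb <- strsplit(read, "")[[1]]
  ab <- strsplit(adapter, "")[[1]]
  for (p in seq_len(L)) {
    o <- min(L - p + 1, A)
    if (o < min_overlap) break
    if (sum(rb[p:(p + o - 1)] != ab[seq_len(o)]) <= max_mismatch) return(p)
  }
  NA_integer_
}

#' Clean, trim and collapse raw small-RNA reads
#'
#' Reads with mean Phred quality below `min_qual` or containing N are
#' discarded; the 3' adapter (if given) is located by the longest
#' adapter-prefix match (minimum 6 nt overlap, at most 1 mismatch) and
#' removed; reads whose trimmed length falls outside `[min_len, max_len]`
#' are discarded; survivors are collapsed to unique sequences with counts.
#' Reads in which no adapter is found are kept untrimmed if their length is
#' already inside the retention window. Cleaning is idempotent.
#'
#' @param reads Tibble with column `seq` (and optionally `qual`, Sanger
#'   Phred+33), e.g. from [read_fastq()], or a character vector of sequences.
#' @param adapter3 3' adapter sequence, or `NULL` to skip trimming.
#' @param min_len,max_len Retention window in nt (defaults 18 and 30).
#' @param min_qual Minimum mean Phred quality (default 20).
#' @param label Tissue label carried on the result.
#' @return A `mulmir_library` (see [new_read_library()]).
#' @export
clean_reads <- function(reads, adapter3 = NULL, min_len = 18, max_len = 30,
                        min_qual = 20, label = "library") {
  if (is.character(reads)) reads <- tibble(seq = reads)
  stopifnot("seq" %in% names(reads))
  wt <- if ("count" %in% names(reads)) as.integer(reads$count)
        else rep(1L, nrow(reads))
  n_raw <- sum(wt)
  seqs <- toupper(reads$seq)

  keep <- rep(TRUE, length(seqs))
  if ("qual" %in% names(reads) && length(seqs) > 0) {
    meanq <- vapply(reads$qual,
                    function(q) mean(utf8ToInt(q)) - 33, numeric(1),
                    USE.NAMES = FALSE)
    keep <- keep & meanq >= min_qual
  }
  seqs <- seqs[keep]
  wt <- wt[keep]

  if (!is.null(adapter3) && length(seqs) > 0) {
    stopifnot(nzchar(adapter3))
    adapter3 <- normalize_alphabet(adapter3)
    uniq <- unique(seqs)
    trim_at <- vapply(uniq, .find_adapter, integer(1), adapter = adapter3,
                      USE.NAMES = TRUE)
    trimmed <- ifelse(is.na(trim_at), uniq, substr(uniq, 1, trim_at - 1))
    seqs <- unname(trimmed[match(seqs, uniq)])
  }
  ok <- !grepl("N", seqs, fixed = TRUE)
  seqs <- normalize_alphabet(seqs[ok])
  wt <- wt[ok]
  len <- nchar(seqs)
  ok <- len >= min_len & len <= max_len
  seqs <- seqs[ok]
  wt <- wt[ok]

  if (length(seqs) == 0) {
    warning("all reads discarded during cleaning", call. = FALSE)
    return(new_read_library(tibble(seq = character(), count = integer()),
                            label = label, total_raw = n_raw))
  }
  agg <- tapply(wt, seqs, sum)
  out <- tibble(seq = names(agg), count = as.integer(agg)) %>%
    arrange(desc(.data$count), .data$seq)
  new_read_library(out, label = label, total_raw = n_raw)
}

#' Read-length distribution of a library
#'
#' Fractions are computed on total (not unique) clean reads and sum to 1.
#'
#' @param lib A `mulmir_library`.
#' @return Tibble with columns `length`, `n_total`, `frac`.
#' @export
length_distribution <- function(lib) {
  stopifnot(inherits(lib, "mulmir_library"))
  if (nrow(lib) == 0 || total_clean(lib) == 0) {
    stop("length distribution of an empty library is undefined", call. = FALSE)
  }
  lib %>%
    mutate(length = nchar(.data$seq)) %>%
    group_by(.data$length) %>%
    summarise(n_total = sum(.data$count), .groups = "drop") %>%
    mutate(frac = .data$n_total / sum(.data$n_total)) %>%
    arrange(.data$length)
}

#' Modal read length
#'
#' @param x A `mulmir_library` or a length-distribution tibble from
#'   [length_distribution()]. Ties are broken towards the smaller length.
#' @return The most frequent read length (integer).
#' @export
modal_length <- function(x) {
  if (inherits(x, "mulmir_library")) x <- length_distribution(x)
  stopifnot(all(c("length", "frac") %in% names(x)), nrow(x) > 0)
  x <- arrange(x, .data$length)
  as.integer(x$length[which.max(x$frac)])
}
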