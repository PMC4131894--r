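#' Nearest-neighbor stack energy table
#'
#' The 6 x 6 table of stacking free energies (kcal/mol) used by the built-in
#' folding and duplex engine, indexed by pair type (`AU`, `UA`, `CG`, `GC`,
#' `GU`, `UG`): entry `[p, q]` is the energy of pair `q` stacked immediately
#' inside pair `p`. Values are Turner-like, symmetrised so a helix has the
#' same energy read from either strand, and clamped to be non-positive.
#'
#' @return A named 6 x 6 numeric matrix.
#' @export
stack_energy_table <- function() .stack_table_cpp()

.encode_seq <- function(seq) {
  s <- normalize_alphabet(seq, "DNA")
  if (grepl("N", s, fixed = TRUE)) {
    stop("cannot fold a sequence containing N", call. = FALSE)
  }
  v <- utf8ToInt(s)
  code <- integer(length(v))
  code[v == utf8ToInt("A")] <- 0L
  code[v == utf8ToInt("C")] <- 1L
  code[v == utf8ToInt("G")] <- 2L
  code[v == utf8ToInt("T")] <- 3L
  code
}

#' Fold a sequence into its minimum-free-energy secondary structure
#'
#' The built-in engine is a Nussinov-style dynamic program scored with the
#' nearest-neighbor stack-energy table of [stack_energy_table()]; hairpin
#' loops are at least 3 nt and loops carry no penalty. `engine = "maxpair"`
#' switches to a unit score of -1 per pair, in which case `|mfe|` equals the
#' maximum attainable number of base pairs (used as a structure oracle).
#'
#' @param seq A single sequence (A/C/G/T/U).
#' @param engine `"stack"` (default, kcal/mol) or `"maxpair"`.
#' @return An object of class `mulmir_fold`: a list with `seq`, `structure`
#'   (dot-bracket), `mfe` (kcal/mol, <= 0), and `pairs` (integer vector of
#'   1-based partners, 0 = unpaired).
#' @export
fold <- function(seq, engine = c("stack", "maxpair")) {
  engine <- match.arg(engine)
  stopifnot(length(seq) == 1, nchar(seq) >= 1)
  code <- .encode_seq(seq)
  res <- .fold_cpp(code, maxpair = (engine == "maxpair"))
  pairs <- res$pairs
  db <- rep(".", length(pairs))
  db[pairs > seq_along(pairs)] <- "("
  db[pairs != 0 & pairs < seq_along(pairs)] <- ")"
  structure(list(seq = normalize_alphabet(seq, "DNA"),
                 structure = paste(db, collapse = ""),
                 mfe = res$energy, pairs = pairs, engine = engine),
            class = "mulmir_fold")
}

#' @export
print.mulmir_fold <- function(x, ...) {
  cat(x$seq, "\n", x$structure, "\n", sep = "")
  cat(sprintf("mfe = %.2f %s\n", x$mfe,
              if (x$engine == "stack") "kcal/mol" else "(-1 per pair)"))
  invisible(x)
}

#' Minimal folding free energy index (MFEI) and adjusted MFE (AMFE)
#'
#' AMFE is `|mfe| / length x 100` (kcal/mol per 100 nt); MFEI is AMFE divided
#' by the GC percentage of the sequence. High MFEI distinguishes miRNA
#' precursors from other RNAs; the discovery filter requires MFEI >= 0.85.
#'
#' @param seq The folded sequence.
#' @param mfe Its minimum free energy (kcal/mol, <= 0).
#' @return A one-row tibble with columns `length`, `gc_percent`, `amfe`,
#'   `mfei`.
#' @export
mfei <- function(seq, mfe) {
  stopifnot(length(seq) == 1, nchar(seq) > 0, length(mfe) == 1)
  s <- normalize_alphabet(seq, "DNA")
  L <- nchar(s)
  gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / L * 100
  if (gc == 0) stop("MFEI undefined for a sequence with no G or C", call. = FALSE)
  amfe <- abs(mfe) / L * 100
  tibble(length = L, gc_percent = gc, amfe = amfe, mfei = amfe / gc)
}

.PAIR_NAMES <- c("AU", "UA", "CG", "GC", "GU", "UG")

#' Ungapped miRNA:site duplex with per-position pair classes
#'
#' Antiparallel pairing of position i of the miRNA (5' to 3') with position
#' L - i + 1 of the site (both given 5' to 3'). Each position is classed
#' `WC`, `GU` or `mismatch`; the weighted mismatch total counts a G:U wobble
#' as 0.5 of a mismatch. Duplex energy is the sum of stack energies over runs
#' of consecutive paired positions.
#'
#' @param mirna,site Equal-length sequences (5' to 3').
#' @return An object of class `mulmir_duplex`: a list with `alignment` (a
#'   tibble: `pos`, `mirna_base`, `site_base`, `class`), `weighted_mismatches`,
#'   `energy` (kcal/mol) and the input sequences.
#' @export
duplex <- function(mirna, site) {
  stopifnot(length(mirna) == 1, length(site) == 1)
  if (nchar(mirna) != nchar(site)) {
    stop("ungapped duplex requires equal lengths (miRNA ", nchar(mirna),
         " nt vs site ", nchar(site), " nt)", call. = FALSE)
  }
  m <- .encode_seq(mirna)
  s <- rev(.encode_seq(site))          # site position L - i + 1 faces miRNA i
  pt <- .pair_type_cpp(m, s)
  class <- ifelse(pt < 0, "mismatch", ifelse(pt >= 4, "GU", "WC"))
  stack <- stack_energy_table()
  paired <- pt >= 0
  energy <- 0
  L <- length(m)
  if (L > 1) {
    both <- paired[-L] & paired[-1]
    if (any(both)) {
      energy <- sum(stack[cbind(pt[-L][both] + 1L, pt[-1][both] + 1L)])
    }
  }
  mb <- strsplit(normalize_alphabet(mirna), "")[[1]]
  sb <- strsplit(normalize_alphabet(site), "")[[1]]
  structure(list(
    alignment = tibble(pos = seq_len(L), mirna_base = mb,
                       site_base = rev(sb), class = class),
    weighted_mismatches = sum(class == "mismatch") + 0.5 * sum(class == "GU"),
    energy = energy, mirna = normalize_alphabet(mirna),
    site = normalize_alphabet(site)), class = "mulmir_duplex")
}

#' @export
print.mulmir_duplex <- function(x, ...) {
  marks <- c(WC = "|", GU = "o", mismatch = ".")
  cat("miRNA 5'-", x$mirna, "-3'\n         ",
      paste(marks[x$alignment$class], collapse = ""), "\n",
      "site  3'-", paste(rev(strsplit(x$site, "")[[1]]), collapse = ""),
      "-5'\n", sep = "")
  cat(sprintf("weighted mismatches = %.1f, energy = %.2f kcal/mol\n",
              x$weighted_mismatches, x$energy))
  invisible(x)
}

#' Duplex energy of a miRNA bound to its perfect complement
#'
#' Reference energy for the target-prediction rule that a candidate duplex
#' must reach at least 75% of the perfect-complement binding energy.
#'
#' @param mirna miRNA sequence (5' to 3').
#' @return Energy in kcal/mol (<= 0).
#' @export
perfect_complement_energy <- function(mirna) {
  duplex(mirna, revcomp(mirna))$energy
}
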