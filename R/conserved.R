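#' Identify conserved miRNAs across tissue libraries
#'
#' A unique read identical (full length, exact, after alphabet
#' normalisation) to a reference mature miRNA becomes one catalog record with
#' per-tissue counts summed from each library; records are deduplicated by
#' sequence. "Perfectly matched" is read strictly: no shifted or trimmed
#' isomiR variants.
#'
#' @param libs Named list of `mulmir_library` objects, one per tissue
#'   (names are the tissue labels; unnamed lists fall back to each library's
#'   own label).
#' @param mature_ref Mature reference tibble from [read_mature_reference()].
#' @param species_code Species prefix for assigned names (default `"mno"`).
#' @return A `mulmir_catalog`: tibble with columns `name`, `ref_name`,
#'   `family`, `seq`, `length` and one count column per tissue, named per
#'   [name_conserved()].
#' @export
identify_conserved <- function(libs, mature_ref, species_code = "mno") {
  stopifnot(is.list(libs), length(libs) > 0)
  if (is.null(names(libs)) || any(!nzchar(names(libs)))) {
    names(libs) <- vapply(libs, library_label, character(1))
  }
  tissues <- names(libs)
  stopifnot(!anyDuplicated(tissues))
  ref <- mature_ref
  if (is.character(ref)) ref <- tibble(name = ref, seq = ref)
  stopifnot(all(c("name", "seq") %in% names(ref)))
  ref$seq <- normalize_alphabet(ref$seq)
  # one reference per distinct sequence (first occurrence wins)
  ref1 <- ref[!duplicated(ref$seq), ]

  counts <- purrr::map(libs, function(l) {
    idx <- match(ref1$seq, l$seq)
    ifelse(is.na(idx), 0L, l$count[idx])
  })
  cnt <- as_tibble(stats::setNames(counts, tissues))
  hit <- rowSums(as.matrix(cnt)) > 0
  rec <- tibble(ref_name = ref1$name, seq = ref1$seq,
                length = nchar(ref1$seq))[hit, ]
  cnt <- cnt[hit, ]
  fam <- rep(NA_character_, nrow(rec))
  has_fam <- grepl("miR[0-9]+", rec$ref_name)
  fam[has_fam] <- parse_family_label(rec$ref_name[has_fam])
  out <- bind_cols(tibble(ref_name = rec$ref_name, family = fam,
                          seq = rec$seq, length = rec$length), cnt)
  out <- name_conserved(out, species_code = species_code, tissues = tissues)
  structure(out, tissues = tissues,
            class = c("mulmir_catalog", "tbl_df", "tbl", "data.frame"))
}

.letter_suffix <- function(k) {
  # a, b, ..., z, aa, ab, ...
  vapply(k, function(i) {
    if (i <= 26) letters[i]
    else paste0(letters[(i - 1) %/% 26], letters[(i - 1) %% 26 + 1])
  }, character(1))
}

#' Assign catalog names within families
#'
#' Members of each family receive suffix letters a, b, c, ... in descending
#' total-count order (the published assignment order is unknowable, so no
#' downstream statistic depends on letters); a family with a single member
#' gets a bare name without a letter, matching the published naming of
#' singleton families. Records without a family keep their reference name.
#'
#' @param records Catalog tibble with `family` and tissue count columns.
#' @param species_code Prefix (default `"mno"`).
#' @param tissues Character vector naming the count columns.
#' @return The tibble with a `name` column, ordered by family then name.
#' @export
name_conserved <- function(records, species_code = "mno", tissues = NULL) {
  if (is.null(tissues)) tissues <- attr(records, "tissues")
  stopifnot(!is.null(tissues), all(tissues %in% names(records)))
  tot <- rowSums(as.matrix(records[, tissues, drop = FALSE]))
  records$.__tot <- tot
  records <- records %>%
    group_by(.data$family) %>%
    arrange(desc(.data$.__tot), .data$seq, .by_group = TRUE) %>%
    mutate(name = dplyr::case_when(
      is.na(.data$family) ~ .data$ref_name,
      dplyr::n() == 1 ~ paste0(species_code, "-", .data$family),
      TRUE ~ paste0(species_code, "-", .data$family,
                    .letter_suffix(row_number())))) %>%
    ungroup() %>%
    select("name", dplyr::everything(), -".__tot")
  records
}

#' Cross-species conservation profile of catalog sequences
#'
#' For each catalog sequence and each species, the distance is the minimum
#' edit distance (unit costs, indels count 1) to any mature miRNA of that
#' species; the symbol is `"++"` at distance 0 (perfect match), `"+"` at
#' 1-3, and `"-"` beyond 3 or when the species set is empty.
#'
#' @param catalog A `mulmir_catalog` (or any tibble with a `seq` column).
#' @param species_sets Named list: species code to a character vector of
#'   mature sequences (or a tibble with a `seq` column).
#' @return The catalog with one symbol column per species appended; the
#'   species columns are recorded in attribute `species`.
#' @export
conservation_profile <- function(catalog, species_sets) {
  stopifnot(is.list(species_sets), length(names(species_sets)) > 0)
  seqs <- normalize_alphabet(catalog$seq)
  for (sp in names(species_sets)) {
    refs <- species_sets[[sp]]
    if (is.data.frame(refs)) refs <- refs$seq
    refs <- if (length(refs)) normalize_alphabet(refs) else character(0)
    if (length(refs) == 0) {
      catalog[[sp]] <- rep("-", length(seqs))
      next
    }
    d <- apply(utils::adist(seqs, refs), 1, min)
    catalog[[sp]] <- ifelse(d == 0, "++", ifelse(d <= 3, "+", "-"))
  }
  attr(catalog, "species") <- union(attr(catalog, "species"),
                                    names(species_sets))
  catalog
}

#' Summary statistics of a conserved-miRNA catalog
#'
#' Presence in a tissue means count > 0; a miRNA is common to all tissues if
#' present in every one. When conservation-profile columns are present, a
#' family's species span is the number of species in which any member is
#' `"+"` or `"++"`; families with span of at most 2 are the "less-conserved"
#' set.
#'
#' @param catalog A `mulmir_catalog`, optionally after
#'   [conservation_profile()].
#' @param tissues Count column names (default: the catalog's `tissues`
#'   attribute).
#' @return One-row tibble: `n_mirnas`, `n_families`, `n_present_<tissue>`,
#'   `n_common_all`, `pct_length_21` and, if profiles are present,
#'   `n_families_span_le2`, `n_families_span_ge3`, `n_exact_all_species`.
#' @export
catalog_stats <- function(catalog, tissues = NULL) {
  if (is.null(tissues)) tissues <- attr(catalog, "tissues")
  stopifnot(nrow(catalog) > 0, !is.null(tissues),
            all(tissues %in% names(catalog)))
  cnt <- as.matrix(catalog[, tissues, drop = FALSE])
  present <- cnt > 0
  out <- tibble(n_mirnas = nrow(catalog),
                n_families = dplyr::n_distinct(catalog$family[!is.na(catalog$family)]))
  for (i in seq_along(tissues)) {
    out[[paste0("n_present_", tissues[i])]] <- sum(present[, i])
  }
  out$n_common_all <- sum(rowSums(present) == length(tissues))
  out$pct_length_21 <- mean(catalog$length == 21) * 100
  species <- attr(catalog, "species")
  if (!is.null(species) && all(species %in% names(catalog))) {
    sym <- as.matrix(catalog[, species, drop = FALSE])
    fam <- catalog$family
    span <- vapply(split(seq_len(nrow(catalog)), fam), function(idx) {
      sum(apply(sym[idx, , drop = FALSE], 2,
                function(col) any(col %in% c("+", "++"))))
    }, integer(1))
    out$n_families_span_le2 <- sum(span <= 2)
    out$n_families_span_ge3 <- sum(span >= 3)
    out$n_exact_all_species <- sum(apply(sym, 1, function(r) all(r == "++")))
  }
  out
}

#' @rdname catalog_stats
#' @param x A `mulmir_catalog`.
#' @param ... Unused.
#' @export
glance.mulmir_catalog <- function(x, ...) catalog_stats(x)

#' Long-format counts of a catalog
#'
#' @param x A `mulmir_catalog`.
#' @param ... Unused.
#' @return Tibble with columns `name`, `family`, `seq`, `tissue`, `count`.
#' @export
tidy.mulmir_catalog <- function(x, ...) {
  tissues <- attr(x, "tissues")
  as_tibble(x) %>%
    select("name", "family", "seq", dplyr::all_of(tissues)) %>%
    tidyr::pivot_longer(dplyr::all_of(tissues), names_to = "tissue",
                        values_to = "count")
}

#' The published conserved-miRNA catalog fixture
#'
#' The 85-record conserved catalog for mulberry leaf, bark and male-flower
#' libraries (name, matched reference, sequence, per-tissue read counts and
#' the seven-species ++/+/- conservation symbols), shipped as a plain-text
#' table and returned as a `mulmir_catalog`.
#'
#' @return A `mulmir_catalog` with tissues `leaf`, `bark`, `male_flower` and
#'   species columns `ath`, `gma`, `mdm`, `ptc`, `rco`, `osa`, `zma`.
#' @export
table2_catalog <- function() {
  path <- system.file("extdata", "table2_conserved.tsv", package = "mulmir")
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  df$seq <- normalize_alphabet(df$seq)
  df$length <- nchar(df$seq)
  structure(as_tibble(df), tissues = c("leaf", "bark", "male_flower"),
            species = c("ath", "gma", "mdm", "ptc", "rco", "osa", "zma"),
            class = c("mulmir_catalog", "tbl_df", "tbl", "data.frame"))
}

#' Published per-library clean-read totals
#'
#' Clean-read totals (reads >= 18 nt) of the three tissue libraries, used as
#' the reads-per-million normalisation denominators.
#'
#' @return Named numeric vector with elements `leaf`, `bark`, `male_flower`.
#' @export
table1_clean_totals <- function() {
  path <- system.file("extdata", "table1_library_sizes.tsv", package = "mulmir")
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stats::setNames(df$total_clean, df$tissue)
}
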