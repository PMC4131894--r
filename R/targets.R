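.RULE_DESCR <- c(
  "weighted mismatches > 4",
  "more than 2 consecutive mismatch positions",
  "adjacent mismatch positions within 2-12",
  "non-Watson-Crick pair at position 10 or 11",
  "weighted mismatches over positions 1-12 > 2.5",
  "duplex energy below 75% of perfect-complement energy")

# Pair-type matrix for all length-L windows of a transcript against a miRNA:
# row = window start (1-based on transcript), column = miRNA position i
# (5'->3'), pairing antiparallel so miRNA i faces window position L-i+1.
.window_pair_types <- function(mirna_code, transcript_code) {
  L <- length(mirna_code)
  nw <- length(transcript_code) - L + 1
  stopifnot(nw >= 1)
  pt <- matrix(-1L, nrow = nw, ncol = L)
  for (i in seq_len(L)) {
    idx <- seq_len(nw) + L - i
    pt[, i] <- .pair_type_cpp(rep.int(mirna_code[i], nw),
                              transcript_code[idx])
  }
  pt
}

# Evaluate all windows given their pair-type matrix. Returns a tibble of
# per-window statistics plus accept/first_violated under the six rules.
.evaluate_windows <- function(pt, mirna, gu_positional = "mismatch") {
  L <- ncol(pt)
  nw <- nrow(pt)
  is_mm <- pt < 0
  is_gu <- pt >= 4
  weighted <- rowSums(is_mm) + 0.5 * rowSums(is_gu)
  core <- seq_len(min(12L, L))
  weighted_core <- rowSums(is_mm[, core, drop = FALSE]) +
    0.5 * rowSums(is_gu[, core, drop = FALSE])
  # positional "mismatch" for adjacency / seed rules; G:U counts by default
  mp <- if (gu_positional == "mismatch") is_mm | is_gu else is_mm

  run3 <- rep(FALSE, nw)
  if (L >= 3) {
    for (j in seq_len(L - 2)) {
      run3 <- run3 | (mp[, j] & mp[, j + 1] & mp[, j + 2])
    }
  }
  adj212 <- rep(FALSE, nw)
  if (L >= 3) {
    for (j in 2:min(11L, L - 1)) {
      adj212 <- adj212 | (mp[, j] & mp[, j + 1])
    }
  }
  core_wc <- if (L >= 11) !(mp[, 10] | mp[, 11]) else rep(TRUE, nw)

  stack <- stack_energy_table()
  energy <- rep(0, nw)
  if (L > 1) {
    for (j in seq_len(L - 1)) {
      both <- pt[, j] >= 0 & pt[, j + 1] >= 0
      if (any(both)) {
        energy[both] <- energy[both] +
          stack[cbind(pt[both, j] + 1L, pt[both, j + 1] + 1L)]
      }
    }
  }
  pe <- perfect_complement_energy(mirna)
  ratio <- if (pe < 0) energy / pe else rep(0, nw)

  viol <- cbind(weighted > 4, run3, adj212, !core_wc,
                weighted_core > 2.5, ratio < 0.75)
  first_violated <- apply(viol, 1, function(v) {
    w <- which(v)
    if (length(w)) w[1] else NA_integer_
  })
  marks <- matrix(".", nw, L)
  marks[!is_mm & !is_gu] <- "|"
  marks[is_gu] <- "o"
  tibble(start = seq_len(nw), end = seq_len(nw) + L - 1,
         weighted_total = weighted, region_1_12_total = weighted_core,
         energy = energy, energy_ratio = ratio,
         accept = is.na(first_violated), first_violated = first_violated,
         alignment = apply(marks, 1, paste, collapse = ""))
}

#' Score a single miRNA:target window under the six complementarity rules
#'
#' Positions are indexed 1..L from the miRNA 5' end. The rules, checked in
#' order: (1) weighted mismatches <= 4 (a G:U wobble counts 0.5); (2) no run
#' of more than 2 consecutive mismatch positions; (3) no two adjacent
#' mismatch positions with both indices in 2-12; (4) positions 10 and 11
#' both Watson-Crick; (5) weighted mismatches over positions 1-12 <= 2.5;
#' (6) duplex energy at least 75% of the miRNA's perfect-complement energy.
#' By default a G:U wobble counts as a mismatch *position* for the
#' positional rules (2)-(4) while contributing 0.5 to the weighted totals;
#' set `gu_positional = "pair"` to treat wobbles as paired there.
#'
#' @param mirna miRNA sequence (5' to 3').
#' @param window Target window of the same length (transcript 5' to 3').
#' @param gu_positional `"mismatch"` (default) or `"pair"`.
#' @return One-row tibble: `weighted_total`, `region_1_12_total`, `energy`,
#'   `energy_ratio`, `accept`, `first_violated` (1-6 or NA), `alignment`
#'   (miRNA 5'->3'; `|` WC, `o` G:U, `.` mismatch).
#' @export
score_site <- function(mirna, window, gu_positional = c("mismatch", "pair")) {
  gu_positional <- match.arg(gu_positional)
  stopifnot(nchar(mirna) == nchar(window))
  pt <- .window_pair_types(.encode_seq(mirna), .encode_seq(window))
  .evaluate_windows(pt, mirna, gu_positional)[, -(1:2)]
}

#' Scan transcripts for miRNA target sites
#'
#' Every length-|miRNA| window of every transcript (sense orientation,
#' ungapped) is evaluated under the six rules of [score_site()]; accepted
#' sites are returned sorted by weighted mismatch total (ascending) then
#' energy ratio (descending).
#'
#' @param mirnas A named character vector of miRNA sequences, a tibble with
#'   columns `name`, `seq`, or a single sequence.
#' @param transcripts Tibble with columns `id`, `seq` (e.g. [read_fasta()]).
#' @param gu_positional Passed to the rule engine; see [score_site()].
#' @param keep_rejected Keep rejected windows too (default `FALSE`).
#' @return Tibble of sites: `mirna`, `transcript`, `start`, `end` (1-based
#'   inclusive), scores as in [score_site()].
#' @export
scan_targets <- function(mirnas, transcripts,
                         gu_positional = c("mismatch", "pair"),
                         keep_rejected = FALSE) {
  gu_positional <- match.arg(gu_positional)
  if (is.character(mirnas) && is.null(names(mirnas))) {
    mirnas <- stats::setNames(mirnas, paste0("miRNA", seq_along(mirnas)))
  }
  if (is.data.frame(mirnas)) {
    mirnas <- stats::setNames(mirnas$seq, mirnas$name)
  }
  stopifnot(all(c("id", "seq") %in% names(transcripts)))
  tcodes <- lapply(transcripts$seq, .encode_seq)
  out <- purrr::imap(mirnas, function(mseq, mname) {
    mcode <- .encode_seq(mseq)
    purrr::map2(transcripts$id, tcodes, function(tid, tc) {
      if (length(tc) < length(mcode)) {
        stop("transcript '", tid, "' (", length(tc),
             " nt) is shorter than miRNA '", mname, "' (", length(mcode),
             " nt)", call. = FALSE)
      }
      res <- .evaluate_windows(.window_pair_types(mcode, tc), mseq,
                               gu_positional)
      res$mirna <- mname
      res$transcript <- tid
      res
    }) %>% bind_rows()
  }) %>% bind_rows()
  if (!keep_rejected) out <- filter(out, .data$accept)
  out %>%
    select("mirna", "transcript", "start", "end", dplyr::everything()) %>%
    arrange(.data$mirna, .data$weighted_total, desc(.data$energy_ratio),
            .data$transcript, .data$start)
}

#' Collapse accepted sites to a per-miRNA target-gene report
#'
#' Distinct target transcripts per miRNA, keeping each transcript's best
#' site (lowest weighted mismatch total, ties by energy ratio).
#'
#' @param sites Output of [scan_targets()].
#' @param annotations Optional tibble with columns `id`, `description`
#'   mapping transcripts to descriptions (missing entries become `"NA"`).
#' @return Tibble: one row per (miRNA, transcript) with the best site and
#'   `description`.
#' @export
annotate_targets <- function(sites, annotations = NULL) {
  if (nrow(sites) == 0) {
    return(tibble(mirna = character(), transcript = character(),
                  start = integer(), end = integer(),
                  weighted_total = numeric(), energy_ratio = numeric(),
                  description = character()))
  }
  best <- sites %>%
    filter(.data$accept) %>%
    group_by(.data$mirna, .data$transcript) %>%
    arrange(.data$weighted_total, desc(.data$energy_ratio),
            .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    ungroup()
  if (!is.null(annotations)) {
    stopifnot(all(c("id", "description") %in% names(annotations)))
    best <- best %>%
      left_join(rename(annotations, transcript = "id"), by = "transcript")
  } else {
    best$description <- NA_character_
  }
  best$description[is.na(best$description)] <- "NA"
  best %>% select("mirna", "transcript", "start", "end", "weighted_total",
                  "energy_ratio", "description")
}
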