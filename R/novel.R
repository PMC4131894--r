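#' Discovery parameter set for novel miRNA prediction
#'
#' Defaults follow the published Mireap-style settings plus the manual
#' hairpin-review criteria: mature length 18-25 nt, reference (seed) read
#' length 20-23 nt, at most 20 genomic copies, precursor free energy below
#' -18 kcal/mol, at most 300 nt between miRNA and miRNA*, at least 16 base
#' pairs in the miRNA:miRNA* duplex, duplex bulge at most 4 nt, duplex
#' asymmetry at most 4 nt, 20-nt precursor flanks, MFEI at least 0.85, fewer
#' than 3 asymmetric bulges and fewer than 4 mismatches in the duplex.
#'
#' @param mirna_len,ref_len Length windows (nt), inclusive.
#' @param max_copies Maximum genomic copy number of a mature sequence.
#' @param max_precursor_mfe Precursor MFE must be strictly below this
#'   (kcal/mol).
#' @param max_star_space Maximum gap between miRNA and miRNA* (nt).
#' @param min_duplex_pairs Minimum paired mature positions in the duplex.
#' @param max_duplex_bulge Maximum single-bulge length (nt).
#' @param max_duplex_asymmetry Maximum overall duplex asymmetry (nt).
#' @param flank Precursor flank length (nt).
#' @param min_mfei Minimum MFEI (inclusive).
#' @param max_manual_bulges Maximum number of asymmetric bulge events
#'   ("less than 3").
#' @param max_manual_mismatches Maximum duplex mismatches ("fewer than 4").
#' @return A named list of class `mulmir_params`.
#' @export
discovery_params <- function(mirna_len = c(18L, 25L), ref_len = c(20L, 23L),
                             max_copies = 20L, max_precursor_mfe = -18,
                             max_star_space = 300L, min_duplex_pairs = 16L,
                             max_duplex_bulge = 4L, max_duplex_asymmetry = 4L,
                             flank = 20L, min_mfei = 0.85,
                             max_manual_bulges = 2L,
                             max_manual_mismatches = 3L) {
  p <- list(mirna_len = as.integer(mirna_len), ref_len = as.integer(ref_len),
            max_copies = as.integer(max_copies),
            max_precursor_mfe = max_precursor_mfe,
            max_star_space = as.integer(max_star_space),
            min_duplex_pairs = as.integer(min_duplex_pairs),
            max_duplex_bulge = as.integer(max_duplex_bulge),
            max_duplex_asymmetry = as.integer(max_duplex_asymmetry),
            flank = as.integer(flank), min_mfei = min_mfei,
            max_manual_bulges = as.integer(max_manual_bulges),
            max_manual_mismatches = as.integer(max_manual_mismatches))
  stopifnot(length(p$mirna_len) == 2, length(p$ref_len) == 2,
            p$max_precursor_mfe < 0, p$min_mfei > 0)
  structure(p, class = c("mulmir_params", "list"))
}

#' Criterion identifiers of the discovery ledger
#'
#' Twelve pass/fail filters (eight Mireap-style structural filters, the
#' copy-number filter applied at catalog level, and the three manual
#' criteria) plus `star_rescue`, which records whether a miRNA* read was
#' observed — not a filter itself but the rescue branch for manual-criterion
#' failures.
#'
#' @return Character vector of criterion ids.
#' @export
discovery_criteria <- function() {
  c("mature_length", "ref_length", "max_copies", "precursor_mfe",
    "star_space", "min_pairs", "duplex_bulge", "duplex_asymmetry", "flank",
    "mfei", "manual_bulges", "manual_mismatches", "star_rescue")
}

.FILTER_CRITERIA <- c("mature_length", "ref_length", "max_copies",
                      "precursor_mfe", "star_space", "min_pairs",
                      "duplex_bulge", "duplex_asymmetry", "flank", "mfei",
                      "manual_bulges", "manual_mismatches")

#' Candidate precursor windows around a mapped read
#'
#' Two windows per locus: one assuming the mature sits on the 5' arm (flank
#' upstream, star-space radius downstream) and one mirrored for the 3' arm.
#' The excision radius is `max_star_space` plus the maximal mature length
#' plus the flank, so a star violating the space bound is still inside the
#' window and fails that specific criterion. Windows are clipped at contig
#' ends; windows shorter than the read plus 40 nt are skipped.
#'
#' @param locus One-row tibble with `chrom`, `start`, `end`, `strand`
#'   (1-based inclusive, as from [match_genome()]).
#' @param genome Tibble with columns `id`, `seq`.
#' @param params A [discovery_params()] list.
#' @return Tibble of windows: `chrom`, `strand`, `arm`, `win_start`,
#'   `win_end` (genomic), `contig_length`, `seq` (oriented 5'->3' along the
#'   precursor strand), `read_start`, `read_len` (in oriented window
#'   coordinates).
#' @export
candidate_precursors <- function(locus, genome, params = discovery_params()) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(locus)),
            nrow(locus) == 1)
  contig <- genome$seq[match(locus$chrom, genome$id)]
  stopifnot(!is.na(contig))
  cl <- nchar(contig)
  radius <- params$max_star_space + params$mirna_len[2] + params$flank
  read_len <- locus$end - locus$start + 1
  plus <- locus$strand == "+"
  # genomic extents: for the 5' arm the flank lies 5' of the mature and the
  # radius 3' of it (in precursor orientation); mirrored for the 3' arm
  ext <- if (plus) {
    list(`5p` = c(locus$start - params$flank, locus$end + radius),
         `3p` = c(locus$start - radius, locus$end + params$flank))
  } else {
    list(`5p` = c(locus$start - radius, locus$end + params$flank),
         `3p` = c(locus$start - params$flank, locus$end + radius))
  }
  rows <- purrr::imap(ext, function(e, arm) {
    ws <- max(1L, e[1])
    we <- min(cl, e[2])
    if (we - ws + 1 < read_len + 40) return(NULL)
    seq <- substr(contig, ws, we)
    if (plus) {
      rs <- locus$start - ws + 1
    } else {
      seq <- revcomp(seq)
      rs <- we - locus$end + 1
    }
    tibble(chrom = locus$chrom, strand = locus$strand, arm = arm,
           win_start = ws, win_end = we, contig_length = cl, seq = seq,
           read_start = rs, read_len = read_len)
  })
  bind_rows(rows)
}

# Walk the mature:star duplex from the fold's pair table and summarise it.
.duplex_stats <- function(pairs, rs, re) {
  m_pos <- rs:re
  partner <- pairs[m_pos]
  paired <- partner != 0
  anchors_m <- m_pos[paired]
  anchors_s <- partner[paired]
  n_pairs <- length(anchors_m)
  mism <- 0L
  bulge_events <- 0L
  max_bulge <- 0L
  asym_m <- 0L
  asym_s <- 0L
  if (n_pairs >= 2) {
    for (k in seq_len(n_pairs - 1)) {
      gap_m <- anchors_m[k + 1] - anchors_m[k] - 1L
      gap_s <- abs(anchors_s[k] - anchors_s[k + 1]) - 1L
      mism <- mism + min(gap_m, gap_s)
      d <- abs(gap_m - gap_s)
      if (d > 0) {
        bulge_events <- bulge_events + 1L
        max_bulge <- max(max_bulge, d)
        if (gap_m > gap_s) asym_m <- asym_m + d else asym_s <- asym_s + d
      }
    }
  }
  # unpaired mature termini count as mismatches (the star was positioned
  # with the 2-nt 3' overhang convention, so terminal overhangs are the
  # star's, not unpaired duplex positions)
  if (n_pairs > 0) {
    mism <- mism + (min(anchors_m) - rs) + (re - max(anchors_m))
  }
  list(n_pairs = n_pairs, mismatches = as.integer(mism),
       bulge_events = bulge_events, max_bulge = as.integer(max_bulge),
       asymmetry = abs(asym_m - asym_s),
       anchors_m = anchors_m, anchors_s = anchors_s)
}

.lib_count_of <- function(libs, seqs) {
  vapply(libs, function(l) {
    idx <- match(seqs, l$seq)
    sum(l$count[idx], na.rm = TRUE)
  }, numeric(1))
}

#' Evaluate a candidate precursor window
#'
#' Folds the window with the built-in engine, requires the read to lie on
#' one arm of the hairpin (reads spanning the terminal loop are rejected),
#' predicts the miRNA* with the 2-nt 3'-overhang convention, computes
#' miRNA:miRNA* duplex statistics, trims the precursor to the hairpin extent
#' plus flanks, re-folds it for MFE and MFEI, and fills the criteria ledger.
#' The star is considered observed when a read matching the predicted star
#' within a 2-nt end-shift tolerance occurs in any library.
#'
#' @param window One-row tibble from [candidate_precursors()].
#' @param libs Named list of `mulmir_library` objects (tissues).
#' @param params A [discovery_params()] list.
#' @return A `mulmir_hairpin` list: `status` (`"ok"` or a rejection reason),
#'   locus and precursor coordinates, `mature_seq`, `arm`, `star_seq`,
#'   duplex statistics, `mfe`, `mfei`, `star_observed`, per-tissue mature
#'   and star counts, and `ledger` (named logical over
#'   [discovery_criteria()]).
#' @export
evaluate_candidate <- function(window, libs, params = discovery_params()) {
  rs <- window$read_start
  re <- rs + window$read_len - 1
  wseq <- window$seq
  L <- nchar(wseq)
  fail_all <- stats::setNames(rep(FALSE, length(discovery_criteria())),
                              discovery_criteria())
  base <- list(status = "ok", chrom = window$chrom, strand = window$strand,
               arm = window$arm, mature_seq = substr(wseq, rs, re),
               ledger = fail_all, star_observed = FALSE)
  f <- fold(wseq)
  partner <- f$pairs[rs:re]
  nz <- partner != 0
  if (!any(nz)) {
    base$status <- "no-pairing"
    class(base) <- "mulmir_hairpin"
    return(base)
  }
  p <- partner[nz]
  if (any(p >= rs & p <= re) || (any(p < rs) && any(p > re))) {
    base$status <- "loop-spanning"
    class(base) <- "mulmir_hairpin"
    return(base)
  }
  m_paired <- (rs:re)[nz]
  s_lo <- min(p) - (re - max(m_paired))
  s_hi <- max(p) + (min(m_paired) - rs) + 2L
  s_lo <- max(1L, s_lo)
  s_hi <- min(L, s_hi)
  if (s_lo <= re && s_hi >= rs) {
    base$status <- "star-overlap"
    class(base) <- "mulmir_hairpin"
    return(base)
  }
  ds <- .duplex_stats(f$pairs, rs, re)
  star_space <- if (s_lo > re) s_lo - re - 1L else rs - s_hi - 1L

  h1 <- min(rs, s_lo)
  h2 <- max(re, s_hi)
  p1 <- max(1L, h1 - params$flank)
  p2 <- min(L, h2 + params$flank)
  prec_seq <- substr(wseq, p1, p2)
  pf <- fold(prec_seq)
  mf <- mfei(prec_seq, pf$mfe)

  # flank availability in the contig around the hairpin extent
  if (window$strand == "+") {
    g1 <- window$win_start + h1 - 1
    g2 <- window$win_start + h2 - 1
  } else {
    g1 <- window$win_end - h2 + 1
    g2 <- window$win_end - h1 + 1
  }
  flank_ok <- (g1 - 1 >= params$flank) &&
    (window$contig_length - g2 >= params$flank)

  # star observation with +/-2 nt end-shift tolerance
  shifts <- expand.grid(a = -2:2, b = -2:2)
  starts <- pmax(1L, s_lo + shifts$a)
  ends <- pmin(L, s_hi + shifts$b)
  vars <- unique(substr(rep(wseq, nrow(shifts)), starts, ends))
  vars <- vars[nchar(vars) >= 15]
  star_counts <- .lib_count_of(libs, vars)
  star_observed <- sum(star_counts) > 0
  mature_counts <- .lib_count_of(libs, base$mature_seq)

  read_len <- window$read_len
  ledger <- c(
    mature_length = read_len >= params$mirna_len[1] &&
      read_len <= params$mirna_len[2],
    ref_length = read_len >= params$ref_len[1] &&
      read_len <= params$ref_len[2],
    max_copies = TRUE, # filled at catalog level
    precursor_mfe = pf$mfe < params$max_precursor_mfe,
    star_space = star_space <= params$max_star_space,
    min_pairs = ds$n_pairs >= params$min_duplex_pairs,
    duplex_bulge = ds$max_bulge <= params$max_duplex_bulge,
    duplex_asymmetry = ds$asymmetry <= params$max_duplex_asymmetry,
    flank = flank_ok,
    mfei = mf$mfei >= params$min_mfei,
    manual_bulges = ds$bulge_events <= params$max_manual_bulges,
    manual_mismatches = ds$mismatches <= params$max_manual_mismatches,
    star_rescue = star_observed)
  ledger <- stats::setNames(unname(ledger), discovery_criteria())

  # genomic precursor and mature coordinates
  if (window$strand == "+") {
    prec <- c(window$win_start + p1 - 1, window$win_start + p2 - 1)
    mat <- c(window$win_start + rs - 1, window$win_start + re - 1)
  } else {
    prec <- c(window$win_end - p2 + 1, window$win_end - p1 + 1)
    mat <- c(window$win_end - re + 1, window$win_end - rs + 1)
  }
  structure(list(
    status = "ok", chrom = window$chrom, strand = window$strand,
    arm = window$arm, mature_seq = base$mature_seq,
    mature_start = mat[1], mature_end = mat[2],
    precursor_start = prec[1], precursor_end = prec[2],
    precursor_seq = prec_seq, structure = pf$structure,
    star_seq = substr(wseq, s_lo, s_hi),
    n_pairs = ds$n_pairs, mismatches = ds$mismatches,
    bulge_events = ds$bulge_events, max_bulge = ds$max_bulge,
    asymmetry = ds$asymmetry, star_space = star_space,
    mfe = pf$mfe, amfe = mf$amfe, mfei = mf$mfei,
    star_observed = star_observed, mature_counts = mature_counts,
    star_counts = star_counts, ledger = ledger), class = "mulmir_hairpin")
}

#' Criteria ledger of a hairpin candidate as a tibble
#'
#' @param x A `mulmir_hairpin`.
#' @param ... Unused.
#' @return Tibble with columns `criterion`, `pass`.
#' @export
tidy.mulmir_hairpin <- function(x, ...) {
  tibble(criterion = names(x$ledger), pass = unname(x$ledger))
}

#' Accept or reject an evaluated candidate
#'
#' The Mireap-style structural filters must all pass; a candidate failing
#' one of the three manual criteria (MFEI, asymmetric-bulge count, mismatch
#' count) is rescued when its miRNA* was observed in a library. Structural
#' failures are never rescued.
#'
#' @param cand A `mulmir_hairpin` from [evaluate_candidate()].
#' @param params A [discovery_params()] list.
#' @return List with `accept` (logical), `branch` (`"criteria"`,
#'   `"star_rescue"` or `"rejected"`), `reason` (character).
#' @export
manual_filter <- function(cand, params = discovery_params()) {
  if (cand$status != "ok") {
    return(list(accept = FALSE, branch = "rejected", reason = cand$status))
  }
  led <- cand$ledger
  mireap <- c("mature_length", "ref_length", "precursor_mfe", "star_space",
              "min_pairs", "duplex_bulge", "duplex_asymmetry", "flank")
  manual <- c("mfei", "manual_bulges", "manual_mismatches")
  if (!all(led[mireap])) {
    return(list(accept = FALSE, branch = "rejected",
                reason = paste("failed:",
                               paste(mireap[!led[mireap]], collapse = ","))))
  }
  if (all(led[manual])) {
    return(list(accept = TRUE, branch = "criteria", reason = "all criteria met"))
  }
  if (cand$star_observed) {
    return(list(accept = TRUE, branch = "star_rescue",
                reason = paste("manual failure rescued by observed miRNA* (",
                               paste(manual[!led[manual]], collapse = ","),
                               ")")))
  }
  list(accept = FALSE, branch = "rejected",
       reason = paste("failed:", paste(manual[!led[manual]], collapse = ",")))
}

#' Predict novel miRNAs from unannotated reads
#'
#' Maps candidate reads to the genome, excises precursor windows, evaluates
#' each window and builds the novel catalog from accepted candidates.
#'
#' @param libs Named list of `mulmir_library` objects.
#' @param genome Tibble with columns `id`, `seq`.
#' @param params A [discovery_params()] list.
#' @param candidate_seqs Reads to consider (default: all unique library
#'   reads within the mature length window). In the full pipeline these are
#'   the unannotated reads from [classify()].
#' @return List with `catalog` (a `mulmir_novel_catalog`), `candidates`
#'   (all evaluated `mulmir_hairpin`s with their filter decisions) and
#'   `loci` (the mapped read loci).
#' @export
discover_novel <- function(libs, genome, params = discovery_params(),
                           candidate_seqs = NULL) {
  if (is.null(candidate_seqs)) {
    candidate_seqs <- unique(unlist(lapply(libs, function(l) l$seq)))
  }
  len <- nchar(candidate_seqs)
  candidate_seqs <-
    candidate_seqs[len >= params$mirna_len[1] & len <= params$mirna_len[2]]
  loci <- match_genome(candidate_seqs, genome)
  cands <- list()
  if (nrow(loci) > 0) {
    for (i in seq_len(nrow(loci))) {
      wins <- candidate_precursors(loci[i, ], genome, params)
      if (nrow(wins) == 0) next
      evs <- lapply(seq_len(nrow(wins)), function(j) {
        ev <- evaluate_candidate(wins[j, ], libs, params)
        ev$decision <- manual_filter(ev, params)
        ev
      })
      ok <- vapply(evs, function(e) e$decision$accept, logical(1))
      pairs <- vapply(evs, function(e) {
        if (e$status == "ok") e$n_pairs else -1L
      }, numeric(1))
      best <- evs[[order(-ok, -pairs)[1]]]
      cands[[length(cands) + 1]] <- best
    }
  }
  catalog <- build_novel_catalog(cands, libs, params)
  list(catalog = catalog, candidates = cands, loci = loci)
}

#' Build the novel miRNA catalog from accepted candidates
#'
#' Accepted candidates are grouped by mature sequence; entries mapping to
#' more than `max_copies` loci are dropped entirely (their ledger entry
#' `max_copies` is set to fail); names `"<prefix>-miRn1"`, `"-miRn2"`, ...
#' are assigned in descending total-count order.
#'
#' @param candidates List of evaluated `mulmir_hairpin`s (with `decision`).
#' @param libs Named list of `mulmir_library` objects.
#' @param params A [discovery_params()] list.
#' @param species_code Name prefix (default `"mno"`).
#' @return A `mulmir_novel_catalog` tibble: `name`, `seq`, `n_loci`,
#'   per-tissue mature counts, per-tissue star counts (`star_<tissue>`),
#'   `mfei`, `star_observed` and a `loci` list-column of coordinate tibbles.
#' @export
build_novel_catalog <- function(candidates, libs,
                                params = discovery_params(),
                                species_code = "mno") {
  tissues <- names(libs)
  acc <- purrr::keep(candidates, function(e) isTRUE(e$decision$accept))
  empty <- tibble(name = character(), seq = character(), n_loci = integer(),
                  mfei = numeric(), star_observed = logical())
  for (t in tissues) empty[[t]] <- numeric(0)
  for (t in tissues) empty[[paste0("star_", t)]] <- numeric(0)
  if (length(acc) == 0) {
    return(structure(empty, tissues = tissues,
                     class = c("mulmir_novel_catalog", "tbl_df", "tbl",
                               "data.frame")))
  }
  mature <- vapply(acc, function(e) e$mature_seq, character(1))
  groups <- split(acc, mature)
  rows <- purrr::imap(groups, function(g, seq) {
    loci <- bind_rows(lapply(g, function(e) {
      tibble(chrom = e$chrom, start = e$precursor_start,
             end = e$precursor_end, strand = e$strand,
             mature_start = e$mature_start, mature_end = e$mature_end)
    })) %>% distinct()
    mc <- .lib_count_of(libs, seq)
    sc <- Reduce(pmax, lapply(g, function(e) e$star_counts))
    row <- tibble(seq = seq, n_loci = nrow(loci),
                  mfei = max(vapply(g, function(e) e$mfei, numeric(1))),
                  star_observed = any(vapply(g, function(e) e$star_observed,
                                             logical(1))))
    for (i in seq_along(tissues)) row[[tissues[i]]] <- mc[i]
    for (i in seq_along(tissues)) row[[paste0("star_", tissues[i])]] <- sc[i]
    row$loci <- list(loci)
    row
  })
  out <- bind_rows(rows)
  # an entry whose mature equals the predicted miRNA* of a more abundant
  # entry (within the 2-nt end tolerance) is that entry's star strand, not
  # an independent miRNA: fold it in (its reads are already counted as
  # star support of the dominant entry)
  star_seqs <- lapply(groups, function(g) {
    unique(vapply(g, function(e) e$star_seq, character(1)))
  })
  tot0 <- rowSums(as.matrix(out[, tissues, drop = FALSE]))
  is_star_pair <- function(a, b) {
    abs(nchar(a) - nchar(b)) <= 4 &&
      (grepl(a, b, fixed = TRUE) || grepl(b, a, fixed = TRUE))
  }
  drop <- vapply(seq_len(nrow(out)), function(i) {
    any(vapply(seq_len(nrow(out)), function(j) {
      j != i && tot0[j] > tot0[i] &&
        any(vapply(star_seqs[[out$seq[j]]], is_star_pair,
                   logical(1), a = out$seq[i]))
    }, logical(1)))
  }, logical(1))
  out <- out[!drop, , drop = FALSE]
  out <- out[out$n_loci <= params$max_copies, , drop = FALSE]
  tot <- rowSums(as.matrix(out[, tissues, drop = FALSE]))
  out <- out[order(-tot, out$seq), , drop = FALSE]
  out$name <- if (nrow(out)) paste0(species_code, "-miRn", seq_len(nrow(out)))
              else character(0)
  out <- out %>% select("name", dplyr::everything())
  structure(out, tissues = tissues,
            class = c("mulmir_novel_catalog", "tbl_df", "tbl", "data.frame"))
}

#' Compare miRNA and miRNA* abundance per tissue
#'
#' @param catalog A `mulmir_novel_catalog`.
#' @return Long tibble: `name`, `tissue`, `mirna_count`, `star_count`,
#'   `star_dominant` (strictly more star than mature reads).
#' @export
star_expression_compare <- function(catalog) {
  tissues <- attr(catalog, "tissues")
  purrr::map(tissues, function(t) {
    tibble(name = catalog$name, tissue = t,
           mirna_count = catalog[[t]],
           star_count = catalog[[paste0("star_", t)]],
           star_dominant = catalog[[paste0("star_", t)]] > catalog[[t]])
  }) %>% bind_rows() %>% arrange(.data$name, .data$tissue)
}
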