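#' Default 3' adapter used by the read simulator
#' @return The adapter sequence (character scalar).
#' @export
default_adapter <- function() "TGGAATTCTCGGGTGCCAAGG"

.COMP <- c(A = "T", C = "G", G = "C", T = "A")

.sample_seq <- function(n, prob = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(prob), n, replace = TRUE, prob = prob), collapse = "")
}

# base that neither Watson-Crick- nor wobble-pairs `b`
.mismatch_base <- function(b) {
  wob <- c(G = "T", T = "G")[b]
  cand <- setdiff(c("A", "C", "G", "T"), c(.COMP[[b]], wob[!is.na(wob)]))
  sample(cand, 1)
}

# Build a miRNA* strand (5'->3') from a mature (5'->3') given a duplex plan:
# mm_pos = symmetric mismatches, m_bulge = mature positions left unpaired
# (mature-side bulge), s_bulge = list of c(after, len) star-side insertions
# placed between the partners of mature positions `after` and `after - 1`.
.make_star <- function(mature, mm_pos = integer(), m_bulge = integer(),
                       s_bulge = list()) {
  mb <- strsplit(mature, "")[[1]]
  L <- length(mb)
  out <- character(0)
  for (i in L:1) {
    if (!(i %in% m_bulge)) {
      out <- c(out, if (i %in% mm_pos) .mismatch_base(mb[i]) else .COMP[[mb[i]]])
    }
    for (sb in s_bulge) {
      if (sb[["after"]] == i) {
        nb <- c(mb[i], if (i > 1) mb[i - 1])
        safe <- Filter(function(b) {
          all(vapply(nb, function(x) {
            !(paste0(x, b) %in% c("AT", "TA", "CG", "GC", "GT", "TG"))
          }, logical(1)))
        }, c("A", "C", "G", "T"))
        if (length(safe) == 0) safe <- "C"
        out <- c(out, sample(safe, sb[["len"]], replace = TRUE))
      }
    }
  }
  paste(out, collapse = "")
}

.flank_seq <- function(n, c_frac = 0.1) {
  .sample_seq(n, prob = c(A = 1 - c_frac, C = c_frac, G = 0, T = 0))
}

# One planted hairpin item. Returns construct (full insert for the genome),
# mature, the actual genomic star string, the mature offset inside the
# construct and which filter criteria the item is expected to fail.
.build_item <- function(kind) {
  flank <- 20L
  loop <- .flank_seq(8, c_frac = 0.3)
  gc_mature <- function(len, gc = 0.55) {
    .sample_seq(len, prob = c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2,
                              T = (1 - gc) / 2))
  }
  mk <- function(mature, mm = integer(), mbul = integer(), sbul = list(),
                 gap = NULL, fl5 = .flank_seq(flank), fl3 = .flank_seq(flank),
                 basal = FALSE, expected = character()) {
    star <- .make_star(mature, mm, mbul, sbul)
    mid <- if (is.null(gap)) loop else gap
    if (basal) {
      # a basal stem below the duplex (as in real pre-miRNAs) stabilises
      # precursors whose duplex carries planted disruptions
      fl5 <- .sample_seq(flank, prob = c(A = 0.35, C = 0.15, G = 0.15,
                                         T = 0.35))
      fl3 <- revcomp(fl5)
    }
    list(construct = paste0(fl5, mature, mid, star, fl3),
         mature = mature, star = star,
         mature_offset = nchar(fl5) + 1L, expected_fail = expected)
  }
  # every stem carries at least one imperfection: a perfect stem would make
  # the mature read an exact reverse complement of its own star, creating a
  # mirror-image genome locus on the other strand
  switch(kind,
    true = {
      len <- sample(20:23, 1)
      mk(gc_mature(len), mm = sample(5:(len - 5), 1),
         expected = character())
    },
    true_imperfect = {
      # one symmetric mismatch and one 1-nt star bulge: still compliant
      len <- 21L
      mk(gc_mature(len, gc = 0.6), mm = 8L,
         sbul = list(c(after = 14L, len = 1L)), basal = TRUE,
         expected = character())
    },
    ref_length = mk(gc_mature(19L, gc = 0.6), mm = 7L,
                    expected = "ref_length"),
    mature_length = mk(gc_mature(26L, gc = 0.6), mm = 9L,
                       expected = c("mature_length", "ref_length")),
    precursor_mfe = {
      # weak AT-rich stem: MFE lands between -18 and 0 while MFEI stays
      # high because the precursor is GC-poor throughout
      m <- gc_mature(20L, gc = 0.2)
      substr(m, 2, 2) <- "G"
      substr(m, 19, 19) <- "C"
      mk(m, mm = c(6L, 14L), fl5 = .flank_seq(flank, 0.05),
         fl3 = .flank_seq(flank, 0.05), expected = "precursor_mfe")
    },
    star_space = {
      m <- gc_mature(21L, gc = 0.7)
      m <- chartr("T", "G", m)        # no T: the poly-A spacer cannot pair it
      mk(m, mm = 11L, gap = strrep("A", 310), expected = "star_space")
    },
    min_pairs = mk(gc_mature(20L, gc = 0.7), mm = c(9L, 10L, 11L),
                   mbul = c(15L, 16L), basal = TRUE,
                   expected = "min_pairs"),
    duplex_bulge = mk(gc_mature(21L, gc = 0.7), mbul = 9:13,
                      sbul = list(c(after = 17L, len = 1L)), basal = TRUE,
                      expected = "duplex_bulge"),
    duplex_asymmetry = mk(gc_mature(21L, gc = 0.7), mbul = c(8:10, 15:16),
                          basal = TRUE, expected = "duplex_asymmetry"),
    flank = {
      it <- mk(gc_mature(21L), mm = 7L, fl5 = .flank_seq(8),
               expected = "flank")
      it$mature_offset <- 9L
      it
    },
    # each copy passes individually; the violation appears at catalog level
    max_copies = mk(gc_mature(21L), mm = 7L, expected = character()),
    mfei = {
      m <- chartr("T", "G", gc_mature(21L, gc = 0.7))
      mk(m, mm = 11L,
         gap = .sample_seq(250, prob = c(A = 0.45, C = 0.55, G = 0, T = 0)),
         expected = "mfei")
    },
    manual_bulges = mk(gc_mature(21L, gc = 0.7), mbul = c(6L, 16L),
                       sbul = list(c(after = 11L, len = 1L)), basal = TRUE,
                       expected = "manual_bulges"),
    manual_mismatches = mk(gc_mature(21L, gc = 0.75),
                           mm = c(5L, 9L, 13L, 17L), basal = TRUE,
                           expected = "manual_mismatches"),
    rescue = {
      m <- chartr("T", "G", gc_mature(21L, gc = 0.7))
      mk(m, mm = 11L,
         gap = .sample_seq(250, prob = c(A = 0.45, C = 0.55, G = 0, T = 0)),
         expected = "mfei")
    },
    stop("unknown item kind: ", kind))
}

# Evaluate a planted item inside a contig and return its best-window ledger.
# g_start is the genomic (plus-strand) start of the mature locus.
.verify_item <- function(contig_id, contig_seq, mature_len, g_start, strand,
                         params) {
  genome <- tibble(id = contig_id, seq = contig_seq)
  locus <- tibble(chrom = contig_id, start = g_start,
                  end = g_start + mature_len - 1, strand = strand)
  wins <- candidate_precursors(locus, genome, params)
  if (nrow(wins) == 0) return(NULL)
  evs <- lapply(seq_len(nrow(wins)), function(j) {
    evaluate_candidate(wins[j, ], libs = list(), params)
  })
  ok <- vapply(evs, function(e) e$status == "ok", logical(1))
  if (!any(ok)) return(NULL)
  evs <- evs[ok]
  np <- vapply(evs, function(e) e$n_pairs, numeric(1))
  evs[[which.max(np)]]
}

#' Generate a synthetic genome with planted and knockout hairpins
#'
#' True hairpins satisfy every discovery criterion under the built-in
#' folding engine; each knockout violates exactly its named criterion (the
#' mature-length decoy necessarily also violates the reference-length
#' criterion, whose bound it contains; the copy-number decoy is planted at
#' `max_copies + 1` identical loci that each pass individually). A rescue
#' hairpin failing only MFEI is planted for the miRNA*-rescue branch.
#' Every item is verified at generation time by running the candidate
#' evaluator on the assembled contig; construction is retried up to 100
#' times per item before failing with the criterion name. Hairpins are
#' separated by at least 500 nt of random background.
#'
#' @param seed Integer seed; identical seeds give identical genomes.
#' @param n_true Number of fully compliant hairpins (default 10).
#' @param knockouts Character vector of filter criterion ids to plant
#'   knockouts for (default: all twelve).
#' @param include_rescue Plant the MFEI-failing rescue hairpin (default
#'   `TRUE`).
#' @param params A [discovery_params()] list.
#' @return List with `genome` (tibble `id`, `seq`) and `truth` (tibble:
#'   `item`, `kind`, `violated`, `chrom`, `strand`, `mature`, `star`,
#'   `mature_start`, `mature_end`, `n_loci`).
#' @export
make_genome <- function(seed, n_true = 10,
                        knockouts = .FILTER_CRITERIA,
                        include_rescue = TRUE,
                        params = discovery_params()) {
  set.seed(seed)
  adapter <- default_adapter()
  spacing <- 520L

  kinds <- c(rep("true", max(0, n_true - 2)),
             rep("true_imperfect", min(2, n_true)))
  items <- tibble(item = paste0("hp_true_", seq_along(kinds)), kind = kinds,
                  violated = NA_character_)
  if (length(knockouts) > 0) {
    stopifnot(all(knockouts %in% .FILTER_CRITERIA))
    items <- bind_rows(items, tibble(item = paste0("hp_ko_", knockouts),
                                     kind = knockouts, violated = knockouts))
  }
  if (include_rescue) {
    items <- bind_rows(items, tibble(item = "hp_rescue", kind = "rescue",
                                     violated = "mfei"))
  }

  contig <- .sample_seq(spacing)
  truth <- list()
  seen_matures <- character(0)
  for (r in seq_len(nrow(items))) {
    kind <- items$kind[r]
    is_edge <- kind == "flank"
    n_copies <- if (kind == "max_copies") params$max_copies + 1L else 1L
    strand <- if (r %% 4 == 3 && !is_edge && kind != "max_copies") "-" else "+"
    done <- FALSE
    for (attempt in 1:100) {
      it <- .build_item(if (kind %in% c("true", "true_imperfect")) kind
                        else kind)
      if (it$mature %in% seen_matures) next
      # the read must survive adapter trimming intact
      if (!identical(.find_adapter(paste0(it$mature, adapter), adapter),
                     nchar(it$mature) + 1L)) next
      if (!identical(.find_adapter(paste0(it$star, adapter), adapter),
                     nchar(it$star) + 1L)) next
      insert <- if (strand == "+") it$construct else revcomp(it$construct)
      # genomic (plus-strand) start of the mature locus within the insert
      off_in_insert <- if (strand == "+") it$mature_offset
        else nchar(insert) - (it$mature_offset + nchar(it$mature) - 1) + 1L
      # verification happens in the exact sequence context that is
      # committed: the trailing spacer is long enough (> window radius)
      # that later items cannot change this item's candidate windows
      if (is_edge) {
        cand_contig <- paste0(insert, .sample_seq(420))
        g_start <- off_in_insert
        cid <- "chr_edge"
      } else {
        cand_contig <- paste0(contig, insert, .sample_seq(spacing))
        g_start <- nchar(contig) + off_in_insert
        cid <- "chr1"
      }
      ev <- .verify_item(cid, cand_contig, mature_len = nchar(it$mature),
                         g_start = g_start, strand = strand, params = params)
      if (is.null(ev)) next
      failed <- names(ev$ledger[.FILTER_CRITERIA])[!ev$ledger[.FILTER_CRITERIA]]
      failed <- setdiff(failed, "max_copies")
      if (!setequal(failed, it$expected_fail %||% character(0))) next
      if (n_copies > 1) {
        # each extra copy is verified in its own committed context too
        ok_copies <- TRUE
        for (cc in seq_len(n_copies - 1)) {
          placed <- FALSE
          for (att2 in 1:100) {
            cand2 <- paste0(cand_contig, insert, .sample_seq(spacing))
            g2 <- nchar(cand_contig) + off_in_insert
            ev2 <- .verify_item(cid, cand2, mature_len = nchar(it$mature),
                                g_start = g2, strand = strand,
                                params = params)
            if (is.null(ev2)) next
            f2 <- names(ev2$ledger[.FILTER_CRITERIA])[!ev2$ledger[.FILTER_CRITERIA]]
            if (!setequal(setdiff(f2, "max_copies"), character(0))) next
            cand_contig <- cand2
            placed <- TRUE
            break
          }
          if (!placed) {
            ok_copies <- FALSE
            break
          }
        }
        if (!ok_copies) next
      }
      # commit
      if (is_edge) {
        edge_contig <- cand_contig
      } else {
        contig <- cand_contig
      }
      seen_matures <- c(seen_matures, it$mature)
      truth[[length(truth) + 1]] <- tibble(
        item = items$item[r], kind = kind, violated = items$violated[r],
        chrom = cid, strand = strand, mature = it$mature, star = it$star,
        mature_start = g_start,
        mature_end = g_start + nchar(it$mature) - 1L,
        n_loci = n_copies)
      done <- TRUE
      break
    }
    if (!done) {
      stop("failed to construct a hairpin satisfying criterion pattern '",
           kind, "' after 100 attempts", call. = FALSE)
    }
  }
  genome <- tibble(id = "chr1", seq = contig)
  if (exists("edge_contig", inherits = FALSE)) {
    genome <- bind_rows(genome, tibble(id = "chr_edge", seq = edge_contig))
  }
  list(genome = genome, truth = bind_rows(truth))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate the planted conserved-miRNA design
#'
#' Nine mature miRNAs in six families with tissue fold-change structure: one
#' leaf-, one bark- and one male-flower-biased family at a planted 3x
#' enrichment (comfortably above the 2x call boundary given multinomial
#' sampling noise at the default depth), the rest unbiased.
#'
#' @param seed Integer seed.
#' @return Tibble: `mature`, `family`, `member`, `base_weight`, per-tissue
#'   relative weights `w_leaf`, `w_bark`, `w_male_flower`, and `bias` (the
#'   intended call).
#' @export
make_conserved_plant <- function(seed) {
  set.seed(seed + 101L)
  fams <- tibble(
    family = c("miR156", "miR156", "miR166", "miR166", "miR172", "miR396",
               "miR396", "miR390", "miR159"),
    member = c("a", "b", "a", "b", "a", "a", "b", "a", "a"),
    base_weight = c(6, 3, 10, 4, 5, 5, 2, 3, 4),
    bias = c("male_flower", "male_flower", "unbiased", "unbiased", "leaf",
             "bark", "bark", "unbiased", "unbiased"))
  adapter <- default_adapter()
  mature <- character(nrow(fams))
  for (i in seq_len(nrow(fams))) {
    repeat {
      m <- .sample_seq(21)
      if (!m %in% mature &&
          identical(.find_adapter(paste0(m, adapter), adapter), 22L)) {
        mature[i] <- m
        break
      }
    }
  }
  fams$mature <- mature
  enrich <- 3
  fams$w_leaf <- fams$base_weight * ifelse(fams$bias == "leaf", enrich, 1)
  fams$w_bark <- fams$base_weight * ifelse(fams$bias == "bark", enrich, 1)
  fams$w_male_flower <- fams$base_weight *
    ifelse(fams$bias == "male_flower", enrich, 1)
  fams
}

#' Generate a multi-species mature reference with controlled distances
#'
#' For each planted conserved miRNA, one variant per species is emitted at
#' edit distance 0, 2 or 5 (cycled deterministically over species so every
#' miRNA has at least one exact entry), giving known expected conservation
#' symbols (0 = `"++"`, 2 = `"+"`, 5 = `"-"`). Distances are verified with
#' [utils::adist()] at generation.
#'
#' @param plant Tibble from [make_conserved_plant()].
#' @param seed Integer seed.
#' @param species Species codes (default the seven comparison species).
#' @return List with `reference` (tibble `name`, `species`, `family`,
#'   `mature` — the source mulberry mature, `seq` — the species variant) and
#'   `expected` (tibble `mature`, `species`, `symbol`).
#' @export
make_species_reference <- function(plant, seed,
                                   species = c("ath", "gma", "mdm", "ptc",
                                               "rco", "osa", "zma")) {
  set.seed(seed + 202L)
  dists <- c(0L, 2L, 5L)
  ref <- list()
  expected <- list()
  for (i in seq_len(nrow(plant))) {
    for (j in seq_along(species)) {
      d <- dists[((i + j) %% 3) + 1]
      m <- plant$mature[i]
      v <- m
      if (d > 0) {
        for (attempt in 1:100) {
          mb <- strsplit(m, "")[[1]]
          pos <- sample(seq_along(mb), d)
          for (p in pos) mb[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                                 mb[p]), 1)
          v <- paste(mb, collapse = "")
          if (utils::adist(v, m) == d) break
          v <- NA_character_
        }
        stopifnot(!is.na(v))
      }
      ref[[length(ref) + 1]] <- tibble(
        name = paste0(species[j], "-", plant$family[i], plant$member[i]),
        species = species[j], family = plant$family[i], mature = m,
        seq = v)
      expected[[length(expected) + 1]] <- tibble(
        mature = m, species = species[j],
        symbol = if (d == 0) "++" else if (d <= 3) "+" else "-")
    }
  }
  list(reference = bind_rows(ref), expected = bind_rows(expected))
}

#' Generate annotation reference sets and matching decoy pools
#'
#' Random reference sequences per non-coding / genic category; decoy reads
#' are drawn from them at library simulation time.
#'
#' @param seed Integer seed.
#' @return A `mulmir_annotation_db` (without genome) whose sets are random
#'   synthetic sequences.
#' @export
make_annotation_refs <- function(seed) {
  set.seed(seed + 303L)
  gen <- function(n, len) vapply(seq_len(n), function(i) .sample_seq(len),
                                 character(1))
  annotation_db(rRNA = gen(3, 600), tRNA = gen(4, 75), snRNA = gen(2, 150),
                snoRNA = gen(2, 120), repeats = gen(3, 400),
                exon = gen(4, 500), intron = gen(4, 500))
}

.LEN_PROFILE_24 <- c(`18` = 0.05, `19` = 0.04, `20` = 0.06, `21` = 0.15,
                     `22` = 0.10, `23` = 0.12, `24` = 0.40, `25` = 0.04,
                     `26` = 0.02, `27` = 0.01, `28` = 0.005, `29` = 0.005)
.LEN_PROFILE_21 <- c(`18` = 0.05, `19` = 0.04, `20` = 0.06, `21` = 0.40,
                     `22` = 0.12, `23` = 0.10, `24` = 0.15, `25` = 0.04,
                     `26` = 0.02, `27` = 0.01, `28` = 0.005, `29` = 0.005)

#' Default per-tissue simulation profiles
#'
#' Class fractions of reads per tissue (planted miRNAs, non-coding decoys,
#' degradation fragments, random background) and the background length
#' profile: 24-nt-dominated for leaf and bark, 21-nt-dominated for male
#' flower, mirroring typical plant tissue small-RNA size distributions.
#'
#' @return Named list of per-tissue profiles.
#' @export
default_tissue_profiles <- function() {
  classes <- c(conserved = 0.08, novel = 0.04, star = 0.004, rRNA = 0.10,
               tRNA = 0.04, snRNA = 0.01, snoRNA = 0.005, repeats = 0.03,
               exon_sense = 0.02, exon_antisense = 0.02,
               intron_sense = 0.015, intron_antisense = 0.015)
  classes <- c(classes, background = 1 - sum(classes))
  list(leaf = list(classes = classes, len_profile = .LEN_PROFILE_24),
       bark = list(classes = classes, len_profile = .LEN_PROFILE_24),
       male_flower = list(classes = classes, len_profile = .LEN_PROFILE_21))
}

.substring_decoys <- function(refs, n, revcomp_frac = 0) {
  if (length(refs) == 0 || n == 0) return(character(0))
  out <- character(n)
  for (i in seq_len(n)) {
    s <- refs[sample(length(refs), 1)]
    len <- sample(19:25, 1)
    st <- sample(nchar(s) - len + 1, 1)
    frag <- substr(s, st, st + len - 1)
    if (stats::runif(1) < revcomp_frac) frag <- revcomp(frag)
    out[i] <- frag
  }
  out
}

#' Simulate three tissue read libraries
#'
#' Reads are sampled with multinomial counts at the given depth from
#' class-weighted pools: planted conserved miRNAs with tissue fold-changes,
#' planted novel/knockout matures, miRNA* reads for the rescue and
#' star-expression cases, decoy fragments of the annotation reference sets,
#' and random background with the tissue's length profile. The 3' adapter
#' is appended to every insert and qualities are constant high ("I").
#'
#' @param genome_truth Truth tibble from [make_genome()] (or `NULL` for a
#'   background-only library).
#' @param plant Conserved design from [make_conserved_plant()] (or `NULL`).
#' @param refs A `mulmir_annotation_db` from [make_annotation_refs()] (or
#'   `NULL`).
#' @param seed Integer seed.
#' @param depth Reads per library (default 50000).
#' @param tissue_profiles See [default_tissue_profiles()].
#' @param adapter 3' adapter appended to inserts.
#' @return List with `reads` (named list of raw-read tibbles `id`, `seq`,
#'   `qual`), `planted_counts` (tibble `seq`, `class`, `tissue`, `count` of
#'   realised planted-read counts) and `star_plan` (which star reads were
#'   planted where).
#' @export
make_libraries <- function(genome_truth, plant, refs, seed, depth = 50000,
                           tissue_profiles = default_tissue_profiles(),
                           adapter = default_adapter()) {
  set.seed(seed + 404L)
  tissues <- names(tissue_profiles)
  for (tp in tissue_profiles) {
    stopifnot(abs(sum(tp$classes) - 1) < 1e-9)
  }

  # star plan: rescue star in bark; first true item's star in all tissues
  # with leaf star-dominant (star > mature in leaf only)
  star_plan <- NULL
  if (!is.null(genome_truth)) {
    rescue <- genome_truth[genome_truth$kind == "rescue", ]
    first_true <- genome_truth[genome_truth$kind == "true", ][1, ]
    star_plan <- bind_rows(
      if (nrow(rescue)) tibble(seq = rescue$star, role = "rescue_star",
                               w_leaf = 0, w_bark = 3, w_male_flower = 0),
      if (nrow(first_true)) tibble(seq = first_true$star,
                                   role = "dominant_star", w_leaf = 6,
                                   w_bark = 0.3, w_male_flower = 0.3))
  }

  pools <- list()
  planted <- list()
  out_reads <- list()
  for (t in tissues) {
    prof <- tissue_profiles[[t]]
    cls <- prof$classes
    pool <- list()
    if (!is.null(plant) && "conserved" %in% names(cls)) {
      w <- plant[[paste0("w_", t)]]
      pool$conserved <- tibble(seq = plant$mature, w = w / sum(w),
                               class = "conserved")
    }
    if (!is.null(genome_truth) && "novel" %in% names(cls)) {
      # the star-dominant mature needs leaf mature < leaf star but a larger
      # total than its star overall
      w <- rep(1, nrow(genome_truth))
      ft <- which(genome_truth$kind == "true")[1]
      if (!is.na(ft)) w[ft] <- if (t == "leaf") 0.35 else 3
      pool$novel <- tibble(seq = genome_truth$mature, w = w / sum(w),
                           class = "novel")
    }
    if (!is.null(star_plan) && nrow(star_plan) > 0 && "star" %in% names(cls)) {
      w <- star_plan[[paste0("w_", t)]]
      if (sum(w) > 0) {
        pool$star <- tibble(seq = star_plan$seq, w = w / sum(w),
                            class = "star")
      }
    }
    if (!is.null(refs)) {
      add_decoys <- function(label, seqs, rc) {
        if (label %in% names(cls) && length(seqs)) {
          d <- .substring_decoys(seqs, 40, revcomp_frac = rc)
          pool[[label]] <<- tibble(seq = d, w = 1 / length(d), class = label)
        }
      }
      add_decoys("rRNA", refs$rRNA, 0.5)
      add_decoys("tRNA", refs$tRNA, 0.5)
      add_decoys("snRNA", refs$snRNA, 0.5)
      add_decoys("snoRNA", refs$snoRNA, 0.5)
      add_decoys("repeats", refs$repeat_, 0.5)
      add_decoys("exon_sense", refs$exon, 0)
      add_decoys("exon_antisense", revcomp(refs$exon), 0)
      add_decoys("intron_sense", refs$intron, 0)
      add_decoys("intron_antisense", revcomp(refs$intron), 0)
    }
    have <- intersect(names(cls), c(names(pool), "background"))
    frac <- cls[have] / sum(cls[have])
    n_per_class <- stats::rmultinom(1, depth, frac)[, 1]
    reads <- character(0)
    for (cl in have) {
      n <- n_per_class[[cl]]
      if (n == 0) next
      if (cl == "background") {
        lens <- sample(as.integer(names(prof$len_profile)), n, replace = TRUE,
                       prob = prof$len_profile)
        bg <- vapply(lens, .sample_seq, character(1))
        reads <- c(reads, bg)
      } else {
        p <- pool[[cl]]
        cnt <- stats::rmultinom(1, n, p$w)[, 1]
        reads <- c(reads, rep(p$seq, cnt))
        planted[[length(planted) + 1]] <-
          tibble(seq = p$seq, class = cl, tissue = t, count = cnt)
      }
    }
    reads <- sample(reads)
    full <- paste0(reads, adapter)
    out_reads[[t]] <- tibble(id = paste0(t, "_r", seq_along(full)),
                             seq = full,
                             qual = strrep("I", nchar(full)))
  }
  planted <- if (length(planted)) bind_rows(planted) else
    tibble(seq = character(), class = character(), tissue = character(),
           count = integer())
  list(reads = out_reads, planted_counts = planted, star_plan = star_plan)
}

#' Design a target miRNA and transcripts with planted sites
#'
#' The miRNA is constructed with wobble-capable bases (G or U) at the
#' positions needed so that each complementarity rule can be violated in
#' isolation (heavier violations use G:U wobbles, which barely perturb the
#' duplex energy, keeping the energy rule satisfied). Twelve compliant sites
#' (perfect, wobble-carrying and single-mismatch variants) and two knockout
#' sites per rule are each embedded in their own transcript; decoy
#' transcripts are random. Every transcript is verified by [scan_targets()]
#' at generation and rebuilt on failure.
#'
#' @param seed Integer seed.
#' @param n_decoys Number of random decoy transcripts (default 12).
#' @return List with `mirna`, `transcripts` (tibble `id`, `seq`,
#'   `description`) and `truth` (tibble `transcript`, `start`,
#'   `violated_rule` with NA for compliant sites).
#' @export
make_transcripts <- function(seed, n_decoys = 12) {
  set.seed(seed + 505L)
  L <- 21L
  need_gt <- c(1, 3, 5, 6, 7, 9, 12, 13, 14, 15, 16, 17, 19)
  repeat {
    mb <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    mb[need_gt] <- sample(c("G", "T"), length(need_gt), replace = TRUE)
    mirna <- paste(mb, collapse = "")
    if (score_site(mirna, revcomp(mirna))$accept) break
  }
  wob <- function(b) c(G = "T", T = "G")[[b]]
  site_for <- function(gu_pos = integer(), mm_pos = integer()) {
    sb <- strsplit(revcomp(mirna), "")[[1]] # site 5'->3'; pos L-i+1 faces i
    for (i in gu_pos) sb[L - i + 1] <- wob(mb[i])
    for (i in mm_pos) sb[L - i + 1] <- .mismatch_base(mb[i])
    paste(sb, collapse = "")
  }
  designs <- list(
    list(id = "perfect", rule = NA_integer_, gu = integer(), mm = integer()),
    list(id = "gu2", rule = NA_integer_, gu = c(14L, 17L), mm = integer()),
    list(id = "mm1", rule = NA_integer_, gu = integer(), mm = 14L),
    list(id = "rule1", rule = 1L, gu = c(1L, 3L, 5L, 7L, 9L, 13L, 15L, 17L,
                                         19L), mm = integer()),
    list(id = "rule2", rule = 2L, gu = c(14L, 15L, 16L), mm = integer()),
    list(id = "rule3", rule = 3L, gu = c(5L, 6L), mm = integer()),
    list(id = "rule4", rule = 4L, gu = integer(), mm = 10L),
    list(id = "rule5", rule = 5L, gu = c(1L, 3L, 5L, 7L, 9L, 12L),
         mm = integer()),
    list(id = "rule6", rule = 6L, gu = integer(),
         mm = c(13L, 15L, 17L, 19L)))
  reps <- c(perfect = 4L, gu2 = 4L, mm1 = 4L, rule1 = 2L, rule2 = 2L,
            rule3 = 2L, rule4 = 2L, rule5 = 2L, rule6 = 2L)
  rows <- list()
  truth <- list()
  for (d in designs) {
    for (k in seq_len(reps[[d$id]])) {
      tid <- paste0("t_", d$id, "_", k)
      ok <- FALSE
      for (attempt in 1:100) {
        site <- site_for(d$gu, d$mm)
        tseq <- paste0(.sample_seq(120), site, .sample_seq(120))
        sc <- scan_targets(stats::setNames(mirna, "m"),
                           tibble(id = tid, seq = tseq),
                           keep_rejected = TRUE)
        acc <- sc[sc$accept, ]
        here <- sc[sc$start == 121L, ]
        expect_accept <- is.na(d$rule)
        if (expect_accept && nrow(acc) == 1 && acc$start == 121) ok <- TRUE
        if (!expect_accept && nrow(acc) == 0 && nrow(here) == 1 &&
            identical(here$first_violated, d$rule)) ok <- TRUE
        if (ok) break
      }
      if (!ok) {
        stop("failed to plant a target site of type '", d$id,
             "' after 100 attempts", call. = FALSE)
      }
      rows[[length(rows) + 1]] <- tibble(
        id = tid, seq = tseq,
        description = paste0("synthetic transcript (", d$id, ")"))
      truth[[length(truth) + 1]] <- tibble(
        transcript = tid, start = 121L, violated_rule = d$rule)
    }
  }
  for (k in seq_len(n_decoys)) {
    tid <- paste0("t_decoy_", k)
    for (attempt in 1:100) {
      tseq <- .sample_seq(280)
      sc <- scan_targets(stats::setNames(mirna, "m"),
                         tibble(id = tid, seq = tseq))
      if (nrow(sc) == 0) break
      tseq <- NULL
    }
    stopifnot(!is.null(tseq))
    rows[[length(rows) + 1]] <- tibble(id = tid, seq = tseq,
                                       description = "synthetic decoy")
  }
  list(mirna = mirna, transcripts = bind_rows(rows), truth = bind_rows(truth))
}

#' Simulate a stem-loop qRT-PCR Ct table
#'
#' One target assay and two reference assays (5.8S rRNA and RPL15) across
#' the three tissues in triplicate. Replicate Cts are the design values plus
#' Gaussian noise (sd `noise_sd`); the designed relative quantities vs the
#' leaf calibrator are 1 (leaf), 0.25 (bark) and 8 (male flower).
#'
#' @param seed Integer seed.
#' @param assay Target assay name.
#' @param noise_sd Replicate noise, Ct units (default 0.05).
#' @return List with `ct` (tibble `assay`, `sample`, `replicate`, `ct`) and
#'   `expected` (tibble `sample`, `rq`).
#' @export
make_ct_table <- function(seed, assay = "mno-miR156a", noise_sd = 0.05) {
  set.seed(seed + 606L)
  samples <- c("leaf", "bark", "male_flower")
  rq <- c(leaf = 1, bark = 0.25, male_flower = 8)
  ref_ct <- c(leaf = 15.2, bark = 15.8, male_flower = 14.9)
  dct_cal <- 6
  rows <- list()
  for (s in samples) {
    dct <- dct_cal - log2(rq[[s]])
    for (a in c(assay, "rRNA5.8S", "RPL15")) {
      base <- if (a == assay) ref_ct[[s]] + dct else
        ref_ct[[s]] + if (a == "rRNA5.8S") -0.4 else 0.4
      rows[[length(rows) + 1]] <- tibble(
        assay = a, sample = s, replicate = 1:3,
        ct = round(base + stats::rnorm(3, 0, noise_sd), 3))
    }
  }
  list(ct = bind_rows(rows),
       expected = tibble(sample = samples, rq = unname(rq[samples])))
}

#' Simulate a complete synthetic dataset with ground truth
#'
#' Drives every generator off a single seed: genome with planted/knockout
#' hairpins, conserved-miRNA design, multi-species reference, annotation
#' reference sets, three tissue libraries, transcripts with planted target
#' sites and a Ct table. All outputs are deterministic in the seed.
#'
#' @param seed Integer seed.
#' @param depth Reads per library (default 50000).
#' @param n_true Number of compliant planted hairpins.
#' @param out_dir Optional directory: writes genome.fa, matures_species.fa,
#'   lib_<tissue>.fastq-style TSVs, transcripts.fa, ct.tsv and truth tables.
#' @param params A [discovery_params()] list.
#' @return List with components `genome`, `genome_truth`, `plant`,
#'   `species_ref`, `refs`, `libraries` (see [make_libraries()]),
#'   `targets` (see [make_transcripts()]), `qpcr` (see [make_ct_table()]).
#' @export
simulate_dataset <- function(seed, depth = 50000, n_true = 10,
                             out_dir = NULL, params = discovery_params()) {
  gen <- make_genome(seed, n_true = n_true, params = params)
  plant <- make_conserved_plant(seed)
  spref <- make_species_reference(plant, seed)
  refs <- make_annotation_refs(seed)
  libs <- make_libraries(gen$truth, plant, refs, seed, depth = depth)
  targ <- make_transcripts(seed)
  qpcr <- make_ct_table(seed)
  out <- list(genome = gen$genome, genome_truth = gen$truth, plant = plant,
              species_ref = spref, refs = refs, libraries = libs,
              targets = targ, qpcr = qpcr, seed = seed, depth = depth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(gen$genome, file.path(out_dir, "genome.fa"))
    write_fasta(tibble(id = spref$reference$name, seq = spref$reference$seq),
                file.path(out_dir, "matures_species.fa"))
    write_fasta(tibble(id = targ$transcripts$id,
                       description = targ$transcripts$description,
                       seq = targ$transcripts$seq),
                file.path(out_dir, "transcripts.fa"))
    readr::write_tsv(qpcr$ct, file.path(out_dir, "ct.tsv"))
    for (t in names(libs$reads)) {
      fq <- libs$reads[[t]]
      writeLines(paste0("@", fq$id, "\n", fq$seq, "\n+\n", fq$qual),
                 file.path(out_dir, paste0("lib_", t, ".fastq")))
    }
    readr::write_tsv(gen$truth, file.path(out_dir, "truth_hairpins.tsv"))
    readr::write_tsv(libs$planted_counts,
                     file.path(out_dir, "truth_counts.tsv"))
    readr::write_tsv(targ$truth, file.path(out_dir, "truth_targets.tsv"))
  }
  out
}
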