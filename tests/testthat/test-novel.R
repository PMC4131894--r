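# Evaluate a truth item's locus the way the discovery stage would, and
# return the best window's evaluated candidate.
eval_truth_item <- function(sim, item, libs = list()) {
  tru <- sim$genome_truth[sim$genome_truth$item == item, ]
  locus <- tibble::tibble(chrom = tru$chrom, start = tru$mature_start,
                          end = tru$mature_end, strand = tru$strand)
  wins <- candidate_precursors(locus, sim$genome)
  evs <- lapply(seq_len(nrow(wins)), function(j) {
    evaluate_candidate(wins[j, ], libs)
  })
  evs <- Filter(function(e) e$status == "ok", evs)
  expect_gt(length(evs), 0)
  evs[[which.max(vapply(evs, function(e) e$n_pairs, numeric(1)))]]
}

test_that("candidate windows bracket the planted precursor", {
  sim <- sim_fixture()
  tru <- sim$genome_truth[sim$genome_truth$kind == "true", ][1, ]
  locus <- tibble::tibble(chrom = tru$chrom, start = tru$mature_start,
                          end = tru$mature_end, strand = tru$strand)
  wins <- candidate_precursors(locus, sim$genome)
  expect_equal(nrow(wins), 2)
  expect_setequal(wins$arm, c("5p", "3p"))
  for (j in 1:2) {
    expect_equal(substr(wins$seq[j], wins$read_start[j],
                        wins$read_start[j] + wins$read_len[j] - 1),
                 tru$mature)
  }
})

test_that("windows near a contig edge are clipped but still usable", {
  set.seed(61)
  genome <- tibble::tibble(id = "c", seq = random_seq(400))
  locus <- tibble::tibble(chrom = "c", start = 11L, end = 31L, strand = "+")
  wins <- candidate_precursors(locus, genome)
  expect_gte(nrow(wins), 1)
  expect_true(all(wins$win_start >= 1 & wins$win_end <= 400))
})

test_that("compliant planted hairpins pass every filter criterion", {
  sim <- sim_fixture()
  true_items <- sim$genome_truth$item[
    sim$genome_truth$kind %in% c("true", "true_imperfect")]
  for (it in true_items) {
    ev <- eval_truth_item(sim, it)
    led <- ev$ledger[setdiff(names(ev$ledger), "star_rescue")]
    expect_true(all(led), info = it)
  }
})

test_that("each knockout decoy fails exactly its violated criterion", {
  sim <- sim_fixture()
  kos <- sim$genome_truth[!is.na(sim$genome_truth$violated) &
                            !sim$genome_truth$kind %in%
                              c("max_copies", "mature_length", "rescue"), ]
  filters <- setdiff(discovery_criteria(), c("star_rescue", "max_copies"))
  for (i in seq_len(nrow(kos))) {
    ev <- eval_truth_item(sim, kos$item[i])
    failed <- names(ev$ledger[filters])[!ev$ledger[filters]]
    expect_equal(failed, kos$violated[i], info = kos$item[i])
    expect_false(manual_filter(ev)$accept, label = kos$item[i])
  }
})

test_that("the over-long decoy fails exactly the two length criteria", {
  sim <- sim_fixture()
  ev <- eval_truth_item(sim, "hp_ko_mature_length")
  filters <- setdiff(discovery_criteria(), c("star_rescue", "max_copies"))
  failed <- names(ev$ledger[filters])[!ev$ledger[filters]]
  expect_setequal(failed, c("mature_length", "ref_length"))
})

test_that("the copy-number decoy is accepted per locus but dropped from the catalog", {
  fx <- pipeline_fixture()
  tru <- fx$sim$genome_truth
  copies <- tru[tru$kind == "max_copies", ]
  ev <- eval_truth_item(fx$sim, copies$item, libs = fx$libs)
  expect_true(manual_filter(ev)$accept)
  loci <- match_genome(copies$mature, fx$sim$genome)
  expect_equal(nrow(loci), copies$n_loci)
  expect_gt(copies$n_loci, discovery_params()$max_copies)
  expect_false(copies$mature %in% fx$disc$catalog$seq)
})

test_that("manual failures are rescued only when the star is observed", {
  fx <- pipeline_fixture()
  tru <- fx$sim$genome_truth
  rescue <- tru[tru$kind == "rescue", ]
  ev <- eval_truth_item(fx$sim, rescue$item, libs = fx$libs)
  expect_false(ev$ledger[["mfei"]])
  expect_true(ev$star_observed)
  dec <- manual_filter(ev)
  expect_true(dec$accept)
  expect_equal(dec$branch, "star_rescue")
  # identical hairpin without the star reads is rejected
  ev2 <- eval_truth_item(fx$sim, rescue$item, libs = list())
  expect_false(manual_filter(ev2)$accept)
  # structural (Mireap-parameter) failures are never rescued
  mfe_ko <- tru[tru$violated %in% "precursor_mfe", ]
  ev3 <- eval_truth_item(fx$sim, mfe_ko$item, libs = fx$libs)
  expect_false(manual_filter(ev3)$accept)
})

test_that("boundary readings are honoured: 'at least', 'less than'", {
  p <- discovery_params()
  led <- stats::setNames(rep(TRUE, 13), discovery_criteria())
  cand <- structure(list(status = "ok", ledger = led, star_observed = FALSE),
                    class = "mulmir_hairpin")
  expect_true(manual_filter(cand, p)$accept)
  led2 <- led
  led2["mfei"] <- FALSE
  cand2 <- structure(list(status = "ok", ledger = led2,
                          star_observed = FALSE), class = "mulmir_hairpin")
  expect_false(manual_filter(cand2, p)$accept)
  cand3 <- structure(list(status = "ok", ledger = led2,
                          star_observed = TRUE), class = "mulmir_hairpin")
  expect_true(manual_filter(cand3, p)$accept)
})

test_that("discovery recovers exactly the planted matures at fixture depth", {
  fx <- pipeline_fixture()
  tru <- fx$sim$genome_truth
  expected <- tru$mature[tru$kind %in% c("true", "true_imperfect", "rescue")]
  got <- fx$disc$catalog$seq
  expect_setequal(got, expected)
  expect_true(all(fx$disc$catalog$n_loci >= 1))
  # every locus can be written as GFF3
  loci <- dplyr::bind_rows(fx$disc$catalog$loci)
  loci$id <- paste0("L", seq_len(nrow(loci)))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_loci_gff(loci, f)
  expect_gte(nrow(read_loci_gff(f)), nrow(fx$disc$catalog))
})

test_that("novel names follow abundance order and star comparison is strict", {
  fx <- pipeline_fixture()
  cat <- fx$disc$catalog
  tissues <- c("leaf", "bark", "male_flower")
  tot <- rowSums(as.matrix(as_tibble(cat)[, tissues]))
  expect_equal(cat$name, paste0("mno-miRn", seq_len(nrow(cat))))
  expect_true(all(diff(tot) <= 0))
  cmp <- star_expression_compare(cat)
  expect_equal(cmp$star_dominant, cmp$star_count > cmp$mirna_count)
  dom <- cmp[cmp$star_dominant & cmp$tissue == "leaf", ]
  expect_gte(nrow(dom), 1)   # the planted leaf star-dominant case
})
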