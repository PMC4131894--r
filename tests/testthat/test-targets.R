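test_that("a perfect complementary site is accepted with zero mismatches", {
  set.seed(51)
  m <- random_seq(21)
  tx <- tibble::tibble(id = "t1",
                       seq = paste0(random_seq(40), revcomp(m),
                                    random_seq(40)))
  hits <- scan_targets(c(mir = m), tx)
  expect_gte(nrow(hits), 1)
  expect_equal(hits$weighted_total[1], 0)
  expect_equal(hits$start[1], 41)
  expect_error(scan_targets(c(mir = m), tibble::tibble(id = "short",
                                                       seq = "ACGTACGT")),
               "shorter")
})

test_that("single rule violations reject with the right first rule", {
  sim <- sim_fixture()
  m <- sim$targets$mirna
  tru <- sim$targets$truth
  all_sites <- scan_targets(c(mir = m), sim$targets$transcripts,
                            keep_rejected = TRUE)
  for (i in seq_len(nrow(tru))) {
    row <- all_sites[all_sites$transcript == tru$transcript[i] &
                       all_sites$start == tru$start[i], ]
    if (is.na(tru$violated_rule[i])) {
      expect_true(row$accept, info = tru$transcript[i])
    } else {
      expect_false(row$accept, info = tru$transcript[i])
      expect_equal(row$first_violated, tru$violated_rule[i],
                   info = tru$transcript[i])
    }
  }
})

test_that("exactly the planted compliant sites are reported", {
  sim <- sim_fixture()
  hits <- scan_targets(c(mir = sim$targets$mirna), sim$targets$transcripts)
  expected <- sim$targets$truth$transcript[
    is.na(sim$targets$truth$violated_rule)]
  expect_setequal(hits$transcript, expected)
  rep <- annotate_targets(hits, sim$targets$transcripts[, c("id",
                                                            "description")])
  expect_equal(sort(rep$transcript), sort(expected))
  expect_false(any(rep$description == "NA"))
})

test_that("scanner equals brute-force window evaluation on short transcripts", {
  set.seed(52)
  for (k in 1:6) {
    m <- random_seq(21)
    tx_seq <- random_seq(sample(60:100, 1))
    got <- scan_targets(c(mir = m), tibble::tibble(id = "t", seq = tx_seq),
                        keep_rejected = TRUE)
    got <- got[order(got$start), ]
    want <- brute_force_scan(m, tx_seq)
    expect_equal(got$accept, want$accept)
    expect_equal(got$first_violated, want$first_violated)
    expect_equal(got$weighted_total, want$weighted_total)
    expect_equal(got$energy, want$energy, tolerance = 1e-9)
  }
})

test_that("position 10/11 wobbles disqualify under the default policy", {
  set.seed(53)
  repeat {
    m <- random_seq(21)
    if (substr(m, 10, 10) %in% c("G", "T")) break
  }
  site <- strsplit(revcomp(m), "")[[1]]
  site[21 - 10 + 1] <- c(G = "T", T = "G")[[substr(m, 10, 10)]]
  site <- paste(site, collapse = "")
  strict <- score_site(m, site)
  expect_false(strict$accept)
  expect_equal(strict$first_violated, 4L)
  lenient <- score_site(m, site, gu_positional = "pair")
  expect_true(lenient$accept)
})

test_that("weighted totals never decrease when a mismatch is added", {
  set.seed(54)
  m <- random_seq(21)
  mb <- strsplit(m, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  wob <- c(G = "T", T = "G")
  site <- strsplit(revcomp(m), "")[[1]]
  base <- score_site(m, paste(site, collapse = ""))
  for (i in c(3, 8, 15)) {
    bad <- c(comp[[mb[i]]], wob[mb[i]])
    site[21 - i + 1] <- setdiff(c("A", "C", "G", "T"), bad[!is.na(bad)])[1]
    worse <- score_site(m, paste(site, collapse = ""))
    expect_gte(worse$weighted_total, base$weighted_total)
    base <- worse
  }
})
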