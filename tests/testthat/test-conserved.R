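test_that("identification requires exact full-length matches and sums tissues", {
  set.seed(31)
  mat <- random_seq(21)
  near <- mat
  substr(near, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                substr(mat, 5, 5))[1]
  libs <- list(
    leaf = new_read_library(tibble::tibble(seq = c(mat, near),
                                           count = c(10L, 99L)),
                            label = "leaf"),
    bark = new_read_library(tibble::tibble(seq = mat, count = 3L),
                            label = "bark"))
  ref <- tibble::tibble(name = "gma-miR156x", seq = mat)
  cat <- identify_conserved(libs, ref)
  expect_equal(nrow(cat), 1)
  expect_equal(cat$leaf, 10)
  expect_equal(cat$bark, 3)
  expect_equal(cat$family, "miR156")
  expect_false(near %in% cat$seq)
})

test_that("suffix letters follow descending abundance; singletons are bare", {
  records <- tibble::tibble(
    ref_name = c("aaa-miR1a", "bbb-miR1b", "ccc-miR2z"),
    family = c("miR1", "miR1", "miR2"),
    seq = c("AAAA", "CCCC", "GGGG"), length = 4L,
    leaf = c(10, 100, 7), bark = c(0, 0, 0))
  named <- name_conserved(records, tissues = c("leaf", "bark"))
  expect_equal(named$name[named$seq == "CCCC"], "mno-miR1a")
  expect_equal(named$name[named$seq == "AAAA"], "mno-miR1b")
  expect_equal(named$name[named$seq == "GGGG"], "mno-miR2")
})

test_that("double letters appear beyond 26 family members", {
  n <- 27
  records <- tibble::tibble(
    ref_name = paste0("sp-miR9x", 1:n), family = "miR9",
    seq = vapply(1:n, function(i) random_seq(20), character(1)),
    length = 20L, leaf = seq(n, 1))
  named <- name_conserved(records, tissues = "leaf")
  expect_equal(named$name[27], "mno-miR9aa")
})

test_that("conservation symbols follow the 0 / 1-3 / >3 distance rule", {
  mat <- random_seq(21)
  v2 <- mat
  substr(v2, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(mat, 3, 3))[1]
  substr(v2, 9, 9) <- setdiff(c("A", "C", "G", "T"), substr(mat, 9, 9))[1]
  cat <- tibble::tibble(seq = mat)
  prof <- conservation_profile(cat, list(
    sp0 = mat, sp2 = v2, sp9 = random_seq(21), spempty = character(0)))
  expect_equal(prof$sp0, "++")
  expect_equal(prof$sp2, "+")
  expect_equal(prof$spempty, "-")
})

test_that("profile recovery is exact for every planted record", {
  fx <- pipeline_fixture()
  cat <- identify_conserved(fx$libs, fx$ref)
  sets <- split(fx$sim$species_ref$reference$seq,
                fx$sim$species_ref$reference$species)
  prof <- conservation_profile(cat, sets)
  exp <- fx$sim$species_ref$expected
  for (i in seq_len(nrow(prof))) {
    for (sp in names(sets)) {
      want <- exp$symbol[exp$mature == prof$seq[i] & exp$species == sp]
      expect_equal(prof[[sp]][i], want,
                   info = paste(prof$name[i], sp))
    }
  }
})

test_that("catalog statistics respect their ordering invariants", {
  fx <- pipeline_fixture()
  cat <- identify_conserved(fx$libs, fx$ref)
  st <- catalog_stats(cat)
  present <- c(st$n_present_leaf, st$n_present_bark, st$n_present_male_flower)
  expect_lte(st$n_common_all, min(present))
  expect_lte(max(present), st$n_mirnas)
})

test_that("the published catalog fixture loads with its full structure", {
  cat <- table2_catalog()
  expect_s3_class(cat, "mulmir_catalog")
  expect_true(all(c("leaf", "bark", "male_flower", "ath", "zma") %in%
                    names(cat)))
  expect_true(all(cat$length == nchar(cat$seq)))
  totals <- table1_clean_totals()
  expect_equal(names(totals), c("leaf", "bark", "male_flower"))
  expect_true(all(totals > 1e7))
})
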