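totals3 <- c(leaf = 1e6, bark = 2e6, male_flower = 5e5)

test_that("RPM is a linear per-column scaling", {
  counts <- tibble::tibble(unit = c("a", "b"), leaf = c(100, 0),
                           bark = c(50, 20), male_flower = c(0, 5))
  ex <- to_rpm(counts, totals3)
  expect_equal(ex$rpm[ex$unit == "a" & ex$tissue == "leaf"], 100)
  expect_equal(ex$rpm[ex$unit == "a" & ex$tissue == "bark"], 25)
  expect_equal(ex$rpm[ex$unit == "b" & ex$tissue == "leaf"], 0)
  expect_error(to_rpm(counts, c(leaf = 0, bark = 1, male_flower = 1)),
               "positive")
})

test_that("family aggregation sums member counts before scaling", {
  cat <- tibble::tibble(name = c("x", "y", "z"),
                        family = c("miR1", "miR1", "miR2"),
                        leaf = c(10, 20, 7), bark = c(1, 2, 3))
  fam <- family_aggregate(cat, tissues = c("leaf", "bark"))
  expect_equal(fam$leaf[fam$family == "miR1"], 30)
  expect_equal(fam$leaf[fam$family == "miR2"], 7)
})

test_that("bias calls use an inclusive 2x boundary and flag specificity", {
  counts <- tibble::tibble(
    unit = c("edge", "spec", "tie", "zero"),
    leaf = c(10, 5, 4, 0), bark = c(4, 0, 4, 0), male_flower = c(5, 0, 4, 0))
  ex <- to_rpm(counts, c(leaf = 1e6, bark = 1e6, male_flower = 1e6))
  calls <- call_bias(ex)
  expect_equal(calls$label[calls$unit == "edge"], "leaf-biased")
  expect_equal(calls$label[calls$unit == "spec"], "leaf-biased")
  expect_equal(calls$specific_to[calls$unit == "spec"], "leaf")
  expect_true(is.na(calls$specific_to[calls$unit == "edge"]))
  expect_equal(calls$label[calls$unit == "tie"], "unbiased")
  expect_equal(calls$label[calls$unit == "zero"], "unbiased")
})

test_that("bias calls are invariant to uniform library rescaling", {
  set.seed(41)
  counts <- tibble::tibble(unit = paste0("u", 1:20),
                           leaf = rpois(20, 50), bark = rpois(20, 50),
                           male_flower = rpois(20, 50))
  a <- call_bias(to_rpm(counts, totals3))
  b <- call_bias(to_rpm(counts, totals3 * 17))
  expect_equal(a$label, b$label)
})

test_that("planted family biases are recovered from simulated libraries", {
  fx <- pipeline_fixture()
  cat <- identify_conserved(fx$libs, fx$ref)
  fam <- family_aggregate(cat)
  calls <- call_bias(to_rpm(fam, vapply(fx$libs, total_clean, numeric(1))))
  want <- unique(fx$sim$plant[, c("family", "bias")])
  for (i in seq_len(nrow(want))) {
    got <- calls$label[calls$unit == want$family[i]]
    expected <- if (want$bias[i] == "unbiased") "unbiased"
                else paste0(want$bias[i], "-biased")
    expect_equal(got, expected, info = want$family[i])
  }
})

test_that("2^-ddCt identities hold: calibrator RQ 1, doubling per -1 ddCt", {
  ct <- tibble::tibble(
    assay = rep(c("mir", "ref1", "ref2"), each = 6),
    sample = rep(rep(c("leaf", "bark"), each = 3), 3),
    replicate = rep(1:3, 6),
    ct = c(21, 21, 21, 20, 20, 20,    # mir: dCt 6 in leaf, 5 in bark
           15, 15, 15, 15, 15, 15,
           15, 15, 15, 15, 15, 15))
  res <- ddct(ct, "mir", c("ref1", "ref2"), "leaf")
  expect_equal(res$rq[res$sample == "leaf"], 1)
  expect_equal(res$ddct[res$sample == "bark"], -1)
  expect_equal(res$rq[res$sample == "bark"], 2)
  # ddCt of log2(10) gives a 10-fold decrease
  ct10 <- ct
  ct10$ct[ct10$assay == "mir" & ct10$sample == "bark"] <- 21 + log2(10)
  res10 <- ddct(ct10, "mir", c("ref1", "ref2"), "leaf")
  expect_equal(res10$rq[res10$sample == "bark"], 0.1)
  expect_error(ddct(ct[ct$assay != "ref2", ], "mir", c("ref1", "ref2"),
                    "leaf"), "no Ct replicates")
})

test_that("simulated Ct tables recover their designed fold changes", {
  q <- make_ct_table(13)
  res <- ddct(q$ct, "mno-miR156a", c("rRNA5.8S", "RPL15"), "leaf")
  m <- merge(res, q$expected, by = "sample")
  expect_true(all(abs(log2(m$rq.x) - log2(m$rq.y)) < 0.3))
})
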