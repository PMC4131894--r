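test_that("generators are deterministic in the seed", {
  g1 <- make_genome(3, n_true = 2, knockouts = c("ref_length", "mfei"),
                    include_rescue = FALSE)
  g2 <- make_genome(3, n_true = 2, knockouts = c("ref_length", "mfei"),
                    include_rescue = FALSE)
  expect_identical(g1, g2)
  p1 <- make_conserved_plant(3)
  expect_identical(p1, make_conserved_plant(3))
  l1 <- make_libraries(g1$truth, p1, make_annotation_refs(3), 3,
                       depth = 2000)
  l2 <- make_libraries(g1$truth, p1, make_annotation_refs(3), 3,
                       depth = 2000)
  expect_identical(l1, l2)
  expect_false(identical(make_conserved_plant(3), make_conserved_plant(4)))
})

test_that("the genome truth table covers true, knockout and rescue items", {
  sim <- sim_fixture()
  tru <- sim$genome_truth
  expect_equal(sum(tru$kind %in% c("true", "true_imperfect")), 10)
  expect_setequal(
    tru$violated[!is.na(tru$violated) & tru$kind != "rescue"],
    setdiff(discovery_criteria(), "star_rescue"))
  expect_equal(tru$violated[tru$kind == "rescue"], "mfei")
  # planted matures are unique and recoverable from the genome
  expect_false(anyDuplicated(tru$mature) > 0)
  for (i in seq_len(nrow(tru))) {
    contig <- sim$genome$seq[sim$genome$id == tru$chrom[i]]
    planted <- substr(contig, tru$mature_start[i], tru$mature_end[i])
    if (tru$strand[i] == "-") planted <- revcomp(planted)
    expect_equal(planted, tru$mature[i], info = tru$item[i])
  }
})

test_that("species variants sit at their designed edit distances", {
  plant <- make_conserved_plant(5)
  ref <- make_species_reference(plant, 5)
  joined <- ref$reference
  d <- mapply(function(a, b) utils::adist(a, b), joined$seq, joined$mature)
  expect_true(all(d %in% c(0, 2, 5)))
  # every planted mature has at least one exact species entry
  exact <- tapply(d, joined$mature, min)
  expect_true(all(exact == 0))
  # expected symbols match the distance rule
  m <- merge(ref$expected,
             data.frame(mature = joined$mature, species = joined$species,
                        d = d))
  expect_true(all((m$d == 0) == (m$symbol == "++")))
  expect_true(all((m$d == 2) == (m$symbol == "+")))
  expect_true(all((m$d == 5) == (m$symbol == "-")))
})

test_that("library class fractions sum to one and planted counts are consistent", {
  sim <- sim_fixture()
  for (t in names(sim$libraries$reads)) {
    pc <- sim$libraries$planted_counts
    pc_t <- pc[pc$tissue == t, ]
    raw <- sim$libraries$reads[[t]]
    inserts <- sub(paste0(default_adapter(), ".*$"), "", raw$seq)
    tab <- table(inserts)
    for (i in sample(seq_len(nrow(pc_t)), 25)) {
      got <- tab[pc_t$seq[i]]
      got <- if (is.na(got)) 0L else as.integer(got)
      expect_equal(got, pc_t$count[i])
    }
  }
  expect_error(make_libraries(NULL, NULL, NULL, 1, depth = 100,
                              tissue_profiles = list(
                                leaf = list(classes = c(background = 0.5),
                                            len_profile = c(`21` = 1)))),
               "1")
})

test_that("simulated FASTQ files round-trip through the readers", {
  td <- withr::local_tempdir()
  sim <- simulate_dataset(9, depth = 500, n_true = 2, out_dir = td)
  expect_true(file.exists(file.path(td, "genome.fa")))
  fq <- read_fastq(file.path(td, "lib_leaf.fastq"))
  expect_equal(nrow(fq), nrow(sim$libraries$reads$leaf))
  g <- read_fasta(file.path(td, "genome.fa"))
  expect_equal(g$seq, sim$genome$seq)
  ct <- read_ct_table(file.path(td, "ct.tsv"))
  expect_equal(nrow(ct), nrow(sim$qpcr$ct))
})
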