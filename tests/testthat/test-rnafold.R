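test_that("forced hairpins fold and homopolymers stay open", {
  f <- fold("GGGGAAAACCCC")
  expect_equal(f$structure, "((((....))))")
  expect_lt(f$mfe, 0)
  h <- fold(strrep("A", 30))
  expect_equal(h$structure, strrep(".", 30))
  expect_equal(h$mfe, 0)
  expect_error(fold("ACGTNACGT"), "N")
})

test_that("folds are well-formed: balanced pairs, loops of at least 3 nt", {
  set.seed(3)
  for (k in 1:10) {
    s <- random_seq(sample(40:200, 1))
    f <- fold(s)
    p <- f$pairs
    idx <- which(p != 0)
    expect_true(all(p[p[idx]] == idx))           # involution
    expect_true(all(abs(idx - p[idx]) >= 4))     # min hairpin loop 3
    n_open <- sum(strsplit(f$structure, "")[[1]] == "(")
    n_close <- sum(strsplit(f$structure, "")[[1]] == ")")
    expect_equal(n_open, n_close)
    expect_equal(n_open, sum(p != 0) / 2)
  }
})

test_that("maxpair mode equals the exhaustive Nussinov pairing oracle", {
  set.seed(5)
  for (k in 1:25) {
    s <- random_seq(sample(8:25, 1))
    expect_equal(-fold(s, engine = "maxpair")$mfe, nussinov_max_pairs(s),
                 info = s)
  }
})

test_that("MFEI follows its defining arithmetic and is scale-invariant", {
  r <- mfei(strrep("GCAT", 25), -42.5)        # L = 100, GC = 50%
  expect_equal(r$amfe, 42.5)
  expect_equal(r$mfei, 0.85)
  expect_equal(mfei(strrep("GCAT", 25), -21)$mfei, 0.42)
  expect_equal(mfei(strrep("GC", 50), -50)$mfei, 0.5)
  s <- random_seq(60)
  f <- fold(s)
  one <- mfei(s, f$mfe)
  two <- mfei(paste0(s, s), 2 * f$mfe)
  expect_equal(one$mfei, two$mfei)
  expect_error(mfei(strrep("AT", 20), -10), "no G or C")
})

test_that("duplex classes and weights follow the G:U half-mismatch rule", {
  m <- "TGGAGAAGCAGGGCACGTGCA"
  d <- duplex(m, revcomp(m))
  expect_true(all(d$alignment$class == "WC"))
  expect_equal(d$weighted_mismatches, 0)
  # flip one site base to create a single G:U wobble (miRNA G faces T)
  gpos <- which(strsplit(m, "")[[1]] == "G")[3]
  site <- strsplit(revcomp(m), "")[[1]]
  site[nchar(m) - gpos + 1] <- "T"
  d2 <- duplex(m, paste(site, collapse = ""))
  expect_equal(sum(d2$alignment$class == "GU"), 1)
  expect_equal(d2$weighted_mismatches, 0.5)
  expect_error(duplex("ACGT", "ACG"), "equal length")
})

test_that("duplex energy is strand-symmetric and worsens with mismatches", {
  set.seed(11)
  for (k in 1:10) {
    a <- random_seq(21)
    b <- random_seq(21)
    expect_equal(duplex(a, b)$energy, duplex(b, a)$energy)
  }
  m <- random_seq(21)
  mb <- strsplit(m, "")[[1]]
  perfect <- duplex(m, revcomp(m))
  site <- strsplit(revcomp(m), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  wob <- c(G = "T", T = "G")
  for (i in c(10, 12)) {
    bad <- c(comp[[mb[i]]], wob[mb[i]])
    site[nchar(m) - i + 1] <- setdiff(c("A", "C", "G", "T"),
                                      bad[!is.na(bad)])[1]
  }
  broken <- duplex(m, paste(site, collapse = ""))
  expect_lte(perfect$energy, broken$energy)
})

test_that("perfect-complement energy is definitional and GC-sensitive", {
  m <- random_seq(21)
  expect_equal(perfect_complement_energy(m),
               duplex(m, revcomp(m))$energy)
  expect_lte(perfect_complement_energy(m), 0)
  gc_rich <- strrep("GC", 11)
  at_rich <- strrep("AT", 11)
  expect_lt(perfect_complement_energy(gc_rich),
            perfect_complement_energy(at_rich))
})

test_that("the stack table is symmetric under strand reversal", {
  s <- stack_energy_table()
  flip <- c(AU = "UA", UA = "AU", CG = "GC", GC = "CG", GU = "UG", UG = "GU")
  for (p in rownames(s)) {
    for (q in colnames(s)) {
      expect_equal(s[p, q], s[flip[[q]], flip[[p]]])
    }
  }
  expect_true(all(s <= 0))
})
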