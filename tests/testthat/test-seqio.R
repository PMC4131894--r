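test_that("FASTA parsing normalises case and alphabet and keeps order", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "acgu", ">y some description", "ACGTN"), f)
  df <- read_fasta(f)
  expect_equal(df$id, c("x", "y"))
  expect_equal(df$seq, c("ACGT", "ACGTN"))
  expect_equal(df$description, c("", "some description"))
  expect_equal(read_fasta(f, alphabet = "RNA")$seq[1], "ACGU")
})

test_that("FASTA degenerate inputs are handled per contract", {
  f <- withr::local_tempfile(fileext = ".fa")
  file.create(f)
  expect_equal(nrow(read_fasta(f)), 0)
  writeLines(c("ACGT", ">x", "ACGT"), f)
  expect_error(read_fasta(f), "malformed FASTA header at line 1")
  writeLines(c(">a", "ACGT", ">empty", "", ">b", "GGGG"), f)
  expect_error(read_fasta(f), "empty")
})

test_that("FASTA round-trips through write_fasta, wrapping at 70 columns", {
  df <- tibble::tibble(id = c("a", "b"),
                       description = c("", "desc text"),
                       seq = c(random_seq(150), random_seq(35)))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(df, f)
  expect_true(all(nchar(readLines(f)) <= 71))
  back <- read_fasta(f)
  expect_equal(back$seq, df$seq)
  expect_equal(back$id, df$id)
})

test_that("alphabet normalisation is idempotent and rejects junk", {
  s <- c("acgu", "ACGT", "nnNN")
  expect_equal(normalize_alphabet(normalize_alphabet(s)),
               normalize_alphabet(s))
  expect_error(normalize_alphabet("ACGX"), "outside")
})

test_that("FASTQ records parse with matched qualities and fail on mismatch", {
  f <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "+", "IIII"), f)
  df <- read_fastq(f)
  expect_equal(nrow(df), 1)
  expect_equal(df$seq, "ACGT")
  writeLines(c("@r1", "ACGT", "+", "II"), f)
  expect_error(read_fastq(f))
  file.create(f2 <- withr::local_tempfile(fileext = ".fq"))
  expect_equal(nrow(read_fastq(f2)), 0)
})

test_that("mature reference names parse into species, family and arm", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">gma-miR156m", "UUGACAGAAGAUAGAGAGCAC",
               ">zma-miR156g-3p", "ACGUACGUACGUACGUACGUA",
               ">xcustom", "ACGU"), f)
  w <- capture_warnings(ref <- read_mature_reference(f))
  expect_match(w, "species", all = FALSE)
  expect_match(w, "family", all = FALSE)
  expect_equal(ref$species, c("gma", "zma", "unknown"))
  expect_equal(ref$family[1:2], c("miR156", "miR156"))
  expect_equal(ref$arm, c(NA, "3p", NA))
  expect_equal(ref$seq[1], "TTGACAGAAGATAGAGAGCAC")
})

test_that("family labels strip letters and arm suffixes", {
  expect_equal(parse_family_label(c("gma-miR156f", "zma-miR156g-3p",
                                    "mtr-miR4414a-5p")),
               c("miR156", "miR156", "miR4414"))
  expect_error(parse_family_label("no-token"), "miR")
})

test_that("GFF3 loci round-trip with 1-based coordinates and verbatim '.'", {
  loci <- tibble::tibble(chrom = c("chr1", "chr1", "chr2"),
                         start = c(100L, 5L, 20L), end = c(200L, 30L, 40L),
                         strand = c("+", "-", "."),
                         id = c("hp1", "hp2", "hp3"))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_loci_gff(loci, f)
  lines <- readLines(f)
  expect_equal(lines[1], "##gff-version 3")
  feat <- strsplit(grep("^[^#]", lines, value = TRUE)[1], "\t")[[1]]
  expect_equal(as.integer(feat[4]), 100L)
  back <- read_loci_gff(f)
  expect_equal(back[order(back$id), c("chrom", "start", "end", "strand", "id")],
               loci[order(loci$id), ], ignore_attr = TRUE)
  # empty set gives a header-only file; start > end errors
  write_loci_gff(loci[0, ], f)
  expect_equal(readLines(f), "##gff-version 3")
  bad <- loci
  bad$start[1] <- 500L
  expect_error(write_loci_gff(bad, f), "start > end")
})

test_that("Ct tables group replicates and reject bad rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("assay\tsample\treplicate\tct",
               "miR156\tleaf\t1\t21.1", "miR156\tleaf\t2\t21.2",
               "miR156\tleaf\t3\t21.3"), f)
  ct <- read_ct_table(f)
  expect_equal(nrow(ct), 3)
  expect_type(ct$ct, "double")
  writeLines(c("assay\tsample\treplicate\tct",
               "miR156\tleaf\t1\tnotanumber"), f)
  expect_error(read_ct_table(f), "non-numeric")
  writeLines(c("assay\tsample\treplicate\tct",
               "miR156\tleaf\t1\t20", "miR156\tleaf\t1\t21"), f)
  expect_error(read_ct_table(f), "duplicated")
})
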