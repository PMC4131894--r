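# Shared synthetic fixtures, generated once per test run at a moderate
# depth; the acceptance suite runs its own full-depth dataset.

.fixture_env <- new.env(parent = emptyenv())

sim_fixture <- function(seed = 7, depth = 20000) {
  key <- paste0("sim_", seed, "_", depth)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_dataset(seed, depth = depth)
  }
  .fixture_env[[key]]
}

# cleaned libraries + annotations + discovery for the shared dataset
pipeline_fixture <- function(seed = 7, depth = 20000) {
  key <- paste0("pipe_", seed, "_", depth)
  if (is.null(.fixture_env[[key]])) {
    sim <- sim_fixture(seed, depth)
    libs <- purrr::imap(sim$libraries$reads, function(r, label) {
      clean_reads(r, adapter3 = default_adapter(), label = label)
    })
    ref <- tibble::tibble(name = sim$species_ref$reference$name,
                          seq = sim$species_ref$reference$seq)
    db <- sim$refs
    db$genome <- sim$genome
    anns <- lapply(libs, classify, db = db, mature_ref = ref)
    unann <- unique(unlist(lapply(anns, function(a) {
      a$seq[a$category == "unannotated"]
    })))
    disc <- discover_novel(libs, sim$genome, candidate_seqs = unann)
    .fixture_env[[key]] <- list(sim = sim, libs = libs, ref = ref, db = db,
                                anns = anns, unann = unann, disc = disc)
  }
  .fixture_env[[key]]
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Independent maximum-pairing oracle (recursive, exhaustive) used to check
# the folding engine's maxpair mode on short sequences.
nussinov_max_pairs <- function(seq) {
  code <- strsplit(seq, "")[[1]]
  n <- length(code)
  can_pair <- function(a, b) {
    paste0(a, b) %in% c("AT", "TA", "CG", "GC", "GT", "TG")
  }
  memo <- new.env(parent = emptyenv())
  f <- function(i, j) {
    if (j - i < 4) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- f(i + 1, j)
    for (k in (i + 4):j) {
      if (can_pair(code[i], code[k])) {
        inner <- if (k - 1 >= i + 1) f(i + 1, k - 1) else 0L
        rest <- if (k + 1 <= j) f(k + 1, j) else 0L
        best <- max(best, 1L + inner + rest)
      }
    }
    memo[[key]] <- best
    best
  }
  f(1, n)
}

# Independent re-implementation of the six-rule site evaluation, written
# against the rule text rather than the scanner's internals.
brute_force_scan <- function(mirna, transcript) {
  L <- nchar(mirna)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  mb <- strsplit(mirna, "")[[1]]
  tb <- strsplit(transcript, "")[[1]]
  stack <- stack_energy_table()
  pt_of <- function(a, b) {
    p <- paste0(a, b)
    c(AT = 1, TA = 2, CG = 3, GC = 4, GT = 5, TG = 6)[p]
  }
  pe <- perfect_complement_energy(mirna)
  out <- list()
  for (s in seq_len(length(tb) - L + 1)) {
    win <- tb[s:(s + L - 1)]
    cls <- character(L)
    pt <- integer(L)
    for (i in seq_len(L)) {
      b <- win[L - i + 1]
      p <- pt_of(mb[i], b)
      if (is.na(p)) {
        cls[i] <- "mismatch"
        pt[i] <- NA
      } else {
        cls[i] <- if (p >= 5) "GU" else "WC"
        pt[i] <- p
      }
    }
    wt <- sum(cls == "mismatch") + 0.5 * sum(cls == "GU")
    core <- 1:12
    wt12 <- sum(cls[core] == "mismatch") + 0.5 * sum(cls[core] == "GU")
    mp <- cls != "WC"
    runs <- rle(mp)
    r2 <- any(runs$values & runs$lengths > 2)
    r3 <- FALSE
    for (j in 2:11) if (mp[j] && mp[j + 1]) r3 <- TRUE
    r4 <- mp[10] || mp[11]
    energy <- 0
    for (i in seq_len(L - 1)) {
      if (!is.na(pt[i]) && !is.na(pt[i + 1])) {
        energy <- energy + stack[pt[i], pt[i + 1]]
      }
    }
    ratio <- if (pe < 0) energy / pe else 0
    viol <- c(wt > 4, r2, r3, r4, wt12 > 2.5, ratio < 0.75)
    first <- if (any(viol)) which(viol)[1] else NA_integer_
    out[[s]] <- tibble::tibble(start = s, accept = !any(viol),
                               first_violated = first, weighted_total = wt,
                               energy = energy, energy_ratio = ratio)
  }
  dplyr::bind_rows(out)
}
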