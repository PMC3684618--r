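test_that("reverse complement handles N, degenerate codes, and is an involution", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AANG"), "CNTT")
  expect_equal(reverse_complement("RYSWKMBDHV"), "BDHVKMWSRY")
  expect_error(reverse_complement("ACGU"), class = "overlapfilter_alphabet_error")
  withr::local_seed(3)
  for (i in 1:20) {
    s <- random_seq(sample(1:80, 1), c("A", "C", "G", "T", "N"))
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("reverse complement agrees with the Biostrings implementation", {
  withr::local_seed(4)
  s <- vapply(1:20, function(i) random_seq(sample(1:60, 1)), character(1))
  ref <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
  expect_equal(reverse_complement(s), unname(ref))
})

test_that("error-free simulated pairs pass and recover their inter-primer region", {
  pairs <- sim_pairs(300, zero_error_model(), seed = 5)
  res <- filter_overlap(pairs, test_design())
  expect_true(all(res$passed))
  expect_identical(res$trimmed_sequence, res$insert)
  expect_identical(res$sample, res$truth_sample)
  expect_equal(nchar(res$trimmed_quality), nchar(res$trimmed_sequence))
  expect_equal(res$n_mismatches, rep(0L, 300))
})

test_that("a single substitution between the primers in one mate fails as MISMATCH", {
  design <- test_design()
  base <- sim_pairs(100, zero_error_model(), seed = 6)
  for (mate in c("r1", "r2")) {
    mut <- inject_substitution(base, design, mate = mate, seed = 7)
    res <- filter_overlap(mut, design)
    expect_true(all(!res$passed), info = mate)
    expect_true(all(res$reason == "MISMATCH"), info = mate)
    expect_true(all(res$n_mismatches == 1L), info = mate)
  }
})

test_that("coincident complementary substitutions in both mates evade the filter", {
  design <- test_design()
  base <- sim_pairs(100, zero_error_model(), seed = 8)
  mut <- inject_coincident(base, design, seed = 9)
  res <- filter_overlap(mut, design)
  expect_true(all(res$passed))
  # the recovered sequence carries the (undetectable) wrong base: exactly one
  # position differs from the true insert
  d <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
              res$trimmed_sequence, res$insert)
  expect_true(all(d == 1L))
})

test_that("ablating a primer anchor yields the matching reason code", {
  design <- test_design()
  pairs <- sim_pairs(40, zero_error_model(), seed = 10)
  read_len <- nchar(pairs$sequence1[1])

  # destroy the distal 6-mer in read 2 (rc2 coordinates -> r2 coordinates)
  ablate_r2_distal <- function(p) {
    offset <- p$construct_len - read_len
    d_rc2 <- p$v6_end2_rc + 1L            # distal starts right after the insert
    lo <- read_len + 1L - (d_rc2 + 5L)
    stringi::stri_sub(p$sequence2, lo, lo + 5L) <- "GGGGGG"  # rc2 becomes CCCCCC
    p
  }
  res <- filter_overlap(ablate_r2_distal(pairs), design)
  expect_true(all(res$reason == "NO_DISTAL_R2"))

  # destroy it in read 1 instead; R1 takes precedence in the reason code
  ablate_r1_distal <- function(p) {
    d1 <- p$v6_end1 + 1L
    stringi::stri_sub(p$sequence1, d1, d1 + 5L) <- "CCCCCC"
    p
  }
  res1 <- filter_overlap(ablate_r1_distal(pairs), design)
  expect_true(all(res1$reason == "NO_DISTAL_R1"))

  # breaking the barcode (outside the primers) is a demultiplexing failure
  bad_bc <- pairs
  stringi::stri_sub(bad_bc$sequence1, 1, 1) <-
    chartr("ACGT", "CAtg", substr(bad_bc$sequence1, 1, 1))
  bad_bc$sequence1 <- toupper(bad_bc$sequence1)
  res_bc <- filter_overlap(bad_bc, design)
  expect_true(all(res_bc$reason == "NO_BARCODE"))
})

test_that("the failure ledger partitions the input by construction", {
  design <- test_design()
  pairs <- sim_pairs(60, zero_error_model(), seed = 12)
  read_len <- nchar(pairs$sequence1[1])
  # 15 distal-ablated in r2, 20 single-mismatch in r1, 25 clean
  idx_ablate <- 1:15
  idx_mm <- 16:35
  d_rc2 <- pairs$v6_end2_rc[idx_ablate] + 1L
  lo <- read_len + 1L - (d_rc2 + 5L)
  stringi::stri_sub(pairs$sequence2[idx_ablate], lo, lo + 5L) <- "GGGGGG"
  mut <- inject_substitution(pairs[idx_mm, ], design, mate = "r1", seed = 13)
  pairs$sequence1[idx_mm] <- mut$sequence1

  res <- filter_overlap(pairs, design)
  ledger <- tally_filter(res, by = "truth_sample")
  expect_equal(sum(ledger$n), nrow(pairs))
  by_reason <- tapply(ledger$n, ledger$reason, sum)
  expect_equal(unname(by_reason[["NO_DISTAL_R2"]]), 15L)
  expect_equal(unname(by_reason[["MISMATCH"]]), 20L)
  expect_equal(unname(by_reason[["OK"]]), 25L)
  expect_equal(unique(ledger$direction[ledger$reason == "NO_DISTAL_R2"]), "R2")

  # empty input: zero rows everywhere, no error
  empty <- filter_overlap(pairs[0, ], design)
  expect_equal(nrow(empty), 0L)
  expect_equal(sum(tally_filter(empty)$n), 0L)
})

test_that("the filter verdict equals a position-wise brute-force oracle on tiny reads", {
  # Tiny geometry: 2-nt barcode, concrete 10-nt proximal, 6-nt distal, 6-nt
  # inserts over {A,C,N} (so no spurious primer motif can arise); both reads
  # span the whole 24-nt construct.
  design <- amplicon_design(c(S = "AC"), "CAACGCGAAG", "AGGTGG")
  read_len <- 24L
  withr::local_seed(21)
  for (i in 1:200) {
    i1 <- random_seq(6, c("A", "C", "N"))
    i2 <- random_seq(6, c("A", "C", "N"))
    c1 <- paste0("AC", "CAACGCGAAG", i1, "AGGTGG")  # 24 nt
    c2 <- paste0("AC", "CAACGCGAAG", i2, "AGGTGG")
    pair <- make_pair_tbl(c1, strrep("I", read_len),
                          reverse_complement(c2), strrep("I", read_len))
    res <- filter_overlap(pair, design)
    ch1 <- strsplit(i1, "")[[1]]; ch2 <- strsplit(i2, "")[[1]]
    oracle_pass <- all(ch1 == ch2 & ch1 != "N" & ch2 != "N")
    expect_equal(res$passed, oracle_pass, info = paste(i1, i2))
    if (oracle_pass) expect_equal(res$trimmed_sequence, i1)
  }
})

test_that("pass rate never increases with the simulator error rate", {
  design <- test_design()
  for (seed in c(31, 32, 33)) {
    rates <- c(0, 0.002, 0.02)
    n <- 1500
    p <- vapply(rates, function(e) {
      pairs <- sim_pairs(n, error_model(base_error_rate = e, ramp_slope = 0,
                                        n_rate = 0, btail_prob = 0), seed = seed)
      mean(filter_overlap(pairs, design)$passed)
    }, numeric(1))
    se <- sqrt(pmax(p * (1 - p), 1e-9) / n)
    expect_gte(p[1], p[2] - 3 * (se[1] + se[2]))
    expect_gte(p[2], p[3] - 3 * (se[2] + se[3]))
  }
})

test_that("coincident-error probability matches exhaustive enumeration of joint outcomes", {
  # Enumerate the 4x4 joint outcomes at one position: each mate keeps the
  # true base with prob 1-e or substitutes each alternative with prob e/3.
  bases <- c("A", "C", "G", "T")
  enum <- function(e, truth = "A") {
    p_of <- function(b) if (b == truth) 1 - e else e / 3
    coincident <- 0
    concordant <- 0
    for (x in bases) for (y in bases) {
      pr <- p_of(x) * p_of(y)
      if (x == y && x != truth) coincident <- coincident + pr
      if (x == y) concordant <- concordant + pr
    }
    c(coincident = coincident, concordant = concordant)
  }
  for (e in c(0.001, 0.01, 0.1)) {
    z <- enum(e)
    expect_equal(prob_coincident_error(e), unname(z["coincident"]), tolerance = 1e-12)
    expect_equal(prob_position_concordant(e), unname(z["concordant"]), tolerance = 1e-12)
  }
})
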