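q40 <- function(n) encode_quality(rep(40L, n))

test_that("run-length quality trimming truncates at the first low-quality run", {
  s <- strrep("A", 10)
  expect_equal(bokulich_trim(s, q40(10))$sequence, s)
  tr <- bokulich_trim(s, encode_quality(c(40, 40, 2, 2, 2, 40, 40, 40, 40, 40)))
  expect_equal(nchar(tr$sequence), 2L)
  expect_equal(nchar(bokulich_trim(s, encode_quality(rep(2, 10)))$sequence), 0L)
  # a run shorter than r does not trigger trimming
  tr2 <- bokulich_trim(s, encode_quality(c(40, 2, 2, 40, 40, 40, 40, 40, 40, 40)))
  expect_equal(nchar(tr2$sequence), 10L)
  # q = 0 is the identity: no quality is < 0
  expect_equal(bokulich_trim(s, encode_quality(rep(0, 10)), q = 0)$sequence, s)
})

test_that("run-length trimming agrees with a brute-force window scan", {
  oracle_keep <- function(qs, q, r) {
    if (length(qs) < r) return(length(qs))
    for (s in seq_len(length(qs) - r + 1)) {
      if (all(qs[s:(s + r - 1)] < q)) return(s - 1L)
    }
    length(qs)
  }
  withr::local_seed(41)
  for (i in 1:400) {
    len <- sample(1:40, 1)
    qs <- sample(0:41, len, replace = TRUE)
    q <- sample(1:20, 1); r <- sample(1:5, 1)
    got <- nchar(bokulich_trim(strrep("A", len), encode_quality(qs), q = q, r = r)$sequence)
    expect_equal(got, oracle_keep(qs, q, r), info = paste(q, r, paste(qs, collapse = ",")))
  }
})

test_that("B-tail trimming strips only the low-quality suffix and is idempotent", {
  s <- strrep("A", 6)
  tr <- btail_trim(s, encode_quality(c(40, 40, 40, 2, 2, 2)))
  expect_equal(nchar(tr$sequence), 3L)
  # interior Q2 bases survive: a B-tail is a suffix
  tr2 <- btail_trim("ACG", encode_quality(c(2, 40, 40)))
  expect_equal(tr2$sequence, "ACG")
  expect_equal(nchar(btail_trim(s, encode_quality(rep(2, 6)))$sequence), 0L)
  withr::local_seed(43)
  for (i in 1:50) {
    len <- sample(1:30, 1)
    qq <- encode_quality(sample(0:41, len, replace = TRUE))
    ss <- random_seq(len)
    once <- btail_trim(ss, qq)
    twice <- btail_trim(once$sequence, once$quality)
    expect_identical(twice, once)
  }
})

test_that("the first-half Q30 criterion matches its boundary semantics exactly", {
  expect_true(minoche_q33(encode_quality(rep(40, 100))))
  # "over Q30" is strict: all-Q30 fails
  expect_false(minoche_q33(encode_quality(rep(30, 100))))
  # h = 6: exactly 4 of the first 6 over Q30 passes (4 = ceiling(2/3 * 6)), 3 fails
  mk <- function(k) encode_quality(c(rep(31, k), rep(30, 6 - k), rep(40, 6)))
  expect_true(minoche_q33(mk(4)))
  expect_false(minoche_q33(mk(3)))
  expect_false(minoche_q33(""))
})

test_that("the first-half criterion agrees with a counting oracle on all patterns", {
  # exhaustive over quality patterns of length 1..10 drawn from {30, 31}
  for (len in 1:10) {
    grid <- expand.grid(rep(list(c(30L, 31L)), len))
    got <- minoche_q33(apply(grid, 1, function(qs) encode_quality(as.integer(qs))))
    want <- apply(grid, 1, function(qs) {
      h <- max(1L, len %/% 2L)
      cnt <- 0L
      for (i in seq_len(h)) if (qs[i] > 30L) cnt <- cnt + 1L
      cnt >= ceiling(2 / 3 * h)
    })
    expect_equal(got, unname(want), info = paste("len", len))
  }
})

test_that("read-level verdicts apply length-ratio and ambiguity rules", {
  # 100-nt read trimmed to 80 passes (0.80 >= 0.75); trimmed to 74 fails
  mkq <- function(keep, len = 100) encode_quality(c(rep(40, keep), rep(0, len - keep)))
  p80 <- make_pair_tbl(strrep("A", 100), mkq(80))
  p74 <- make_pair_tbl(strrep("A", 100), mkq(74))
  expect_true(filter_qscore(p80, "bokulich")$passed)
  res74 <- filter_qscore(p74, "bokulich")
  expect_false(res74$passed)
  expect_equal(as.character(res74$reason), "TRIM_LENGTH")
  # an untrimmed read with one N fails at n = 0
  pN <- make_pair_tbl(paste0(strrep("A", 50), "N", strrep("A", 49)), q40(100))
  resN <- filter_qscore(pN, "bokulich")
  expect_equal(as.character(resN$reason), "AMBIGUOUS")
  # B-tail of 30 nt on a 101-nt read fails the minoche length rule (71/101 < 0.75)
  pB <- make_pair_tbl(strrep("A", 101),
                      encode_quality(c(rep(40, 71), rep(2, 30))))
  resB <- filter_qscore(pB, "minoche")
  expect_equal(as.character(resB$reason), "TRIM_LENGTH")
  # B-tail-free read failing only the first-half criterion
  pQ <- make_pair_tbl(strrep("A", 100), encode_quality(c(rep(30, 50), rep(40, 50))))
  resQ <- filter_qscore(pQ, "minoche")
  expect_equal(as.character(resQ$reason), "Q33")
})

test_that("a pair is discarded when either mate fails, with per-read accounting", {
  good <- q40(100)
  bad <- encode_quality(c(rep(40, 50), rep(0, 50)))
  s <- strrep("A", 100)
  both <- filter_qscore(make_pair_tbl(s, good, s, good), "bokulich")
  expect_true(both$passed)
  r2bad <- filter_qscore(make_pair_tbl(s, good, s, bad), "bokulich")
  expect_false(r2bad$passed)
  expect_equal(as.character(r2bad$reason), "TRIM_LENGTH")
  expect_equal(as.character(r2bad$reason1), "MATE_FAILED")
  expect_equal(as.character(r2bad$reason2), "TRIM_LENGTH")
  neither <- filter_qscore(make_pair_tbl(s, bad, s, bad), "bokulich")
  expect_false(neither$passed)
  expect_equal(as.character(neither$reason1), "TRIM_LENGTH")
})

test_that("passing the trimming filter is monotone in all four parameters", {
  withr::local_seed(47)
  pair_pass <- function(qs, params) {
    n <- length(qs)
    seqs <- strrep("A", n)
    filter_qscore(make_pair_tbl(seqs, encode_quality(qs)), "bokulich", params)$passed
  }
  for (i in 1:60) {
    qs <- sample(0:41, sample(20:101, 1), replace = TRUE)
    p <- runif(1, 0.3, 1); q <- sample(1:10, 1); r <- sample(1:4, 1); n <- sample(0:2, 1)
    if (pair_pass(qs, bokulich_params(p, q, r, n))) {
      relaxed <- bokulich_params(max(p - runif(1, 0, 0.2), 0.01),
                                 max(q - sample(0:3, 1), 0L),
                                 r + sample(0:3, 1), n + sample(0:3, 1))
      expect_true(pair_pass(qs, relaxed),
                  info = sprintf("p=%.2f q=%d r=%d n=%d", p, q, r, n))
    }
  }
})

test_that("miscalibrated runs: Q-score filters pass error-bearing pairs the overlap filter rejects", {
  design <- test_design()
  model <- error_model(base_error_rate = 0.01, ramp_slope = 0, n_rate = 0.001,
                       btail_prob = 0.05, miscalibration = TRUE)
  for (seed in c(51, 52, 53)) {
    pairs <- sim_pairs(1200, model, seed = seed)
    ov <- filter_overlap(pairs, design)
    bk <- filter_qscore(pairs, "bokulich")
    mn <- filter_qscore(pairs, "minoche")
    expect_gt(mean(bk$passed), mean(ov$passed))
    expect_gt(mean(mn$passed), mean(ov$passed))
    # specifically: pairs carrying true inter-primer errors slip through the
    # Q-score filters but not the overlap filter
    erroneous <- pairs$n_v6_err1 > 0 | pairs$n_v6_err2 > 0
    expect_gt(mean(bk$passed[erroneous]), mean(ov$passed[erroneous]))
    expect_lt(mean(ov$passed[erroneous]), 0.01)
  }
})
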