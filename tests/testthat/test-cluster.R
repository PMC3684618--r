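test_that("identity arithmetic matches the 62-nt clustering rationale", {
  withr::local_seed(61)
  a <- random_seq(62)
  expect_equal(seq_identity(a, a), 1)
  sub_at <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- setdiff(c("A", "C", "G", "T"), ch[pos])[1]
    paste(ch, collapse = "")
  }
  one <- sub_at(a, 10)
  two <- sub_at(one, 30)
  expect_equal(seq_identity(a, one), 1 - 1 / 62)
  expect_gte(seq_identity(a, one), 0.97)   # 1 substitution clusters at 97%
  expect_equal(seq_identity(a, two), 1 - 2 / 62)
  expect_lt(seq_identity(a, two), 0.97)    # 2 substitutions split at 97%
  # symmetry; length difference handled by longer-length normalisation
  expect_equal(seq_identity(a, two), seq_identity(two, a))
  expect_equal(seq_identity("ACGTACGT", "ACGT"), 0.5)
})

test_that("greedy clustering follows abundance order, threshold and size filter", {
  withr::local_seed(62)
  a <- random_seq(62)
  ch <- strsplit(a, "")[[1]]
  b1 <- a; substr(b1, 5, 5) <- setdiff(c("A", "C", "G", "T"), ch[5])[1]
  b3 <- a
  for (p in c(5, 20, 40)) substr(b3, p, p) <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  cs <- cluster_greedy(rep(a, 10))
  expect_equal(tidy(cs)$size, 10L)
  expect_equal(n_otus(cs), 1L)

  # 5 x A + 3 x B one substitution apart: one cluster of 8, representative A
  cs2 <- cluster_greedy(c(rep(a, 5), rep(b1, 3)))
  expect_equal(n_otus(cs2), 1L)
  expect_equal(tidy(cs2)$representative, a)
  expect_equal(tidy(cs2)$size, 8L)

  # 3 substitutions apart plus a singleton: two retained clusters
  singleton <- random_seq(62)
  cs3 <- cluster_greedy(c(rep(a, 5), rep(b3, 3), singleton))
  expect_equal(n_otus(cs3), 2L)
  expect_equal(sum(tidy(cs3, all = TRUE)$size), 9L)  # counts partition the input

  # input order must not matter
  reads <- c(rep(a, 5), rep(b3, 3), singleton)
  cs4 <- cluster_greedy(sample(reads))
  expect_identical(tidy(cs4, all = TRUE), tidy(cs3, all = TRUE))
})

test_that("threshold 1.0 clustering equals dereplication with a size cut", {
  withr::local_seed(63)
  pool <- vapply(1:8, function(i) random_seq(20), character(1))
  reads <- sample(pool, 300, replace = TRUE, prob = c(8, 6, 4, 3, 2, 2, 1, 1))
  cs <- cluster_greedy(reads, threshold = 1, min_size = 2)
  derep <- table(reads)
  expect_equal(n_otus(cs), sum(derep >= 2))
  got <- tidy(cs, all = TRUE)
  expect_equal(got$size[order(got$representative)],
               unname(as.integer(derep[order(names(derep))])))
})

test_that("cluster count is non-increasing as the threshold decreases", {
  withr::local_seed(64)
  base <- random_seq(62)
  reads <- vapply(1:120, function(i) {
    s <- base
    k <- sample(0:4, 1)
    if (k > 0) {
      for (p in sample(62, k)) {
        substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), substr(s, p, p)), 1)
      }
    }
    s
  }, character(1))
  counts <- vapply(c(1.0, 0.97, 0.90, 0.80), function(th) {
    nrow(tidy(cluster_greedy(reads, threshold = th, min_size = 1), all = TRUE))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("greedy clustering agrees with an independent small-instance oracle", {
  # Independent oracle: a direct transliteration of the clustering rule using
  # seq_identity(), plus the structural guarantee that representatives are
  # mutually below the threshold.
  oracle <- function(reads, threshold) {
    tab <- sort(table(reads), decreasing = TRUE)
    uniq <- names(tab)[order(-as.integer(tab), names(tab))]
    reps <- character(0)
    for (u in uniq) {
      hit <- FALSE
      for (rp in reps) {
        if (seq_identity(u, rp) >= threshold) { hit <- TRUE; break }
      }
      if (!hit) reps <- c(reps, u)
    }
    reps
  }
  withr::local_seed(65)
  for (i in 1:40) {
    pool <- unique(vapply(1:8, function(j) random_seq(sample(6:10, 1), c("A", "C")),
                          character(1)))
    reads <- sample(pool, 30, replace = TRUE)
    th <- sample(c(0.7, 0.8, 0.9), 1)
    cs <- cluster_greedy(reads, threshold = th, min_size = 1)
    reps <- tidy(cs, all = TRUE)$representative
    expect_setequal(reps, oracle(reads, th))
    if (length(reps) > 1) {
      pairwise <- outer(reps, reps, Vectorize(function(x, y) seq_identity(x, y)))
      expect_true(all(pairwise[upper.tri(pairwise)] < th))
    }
  }
})

test_that("equal-depth subsampling reports means, ratios and is reproducible", {
  withr::local_seed(66)
  pool <- vapply(1:5, function(i) random_seq(62), character(1))
  b <- rep(pool, each = 20)
  # extra error-bearing unique singletons do not change the OTU mean
  junk <- vapply(1:100, function(i) random_seq(62), character(1))
  a <- c(b, junk)
  rep1 <- subsample_compare(list(A = a, B = b), replicates = 5, seed = 99)
  expect_equal(rep1$depth, 100L)
  g <- glance(rep1)
  expect_equal(g$mean_otus[g$method == "A"], g$mean_otus[g$method == "B"])
  expect_equal(g$ratio, c(1, 1))
  expect_equal(tidy(rep1)$n_otus[tidy(rep1)$method == "B"], rep(5L, 5))

  rep2 <- subsample_compare(list(A = a, B = b), replicates = 5, seed = 99)
  expect_identical(tidy(rep1), tidy(rep2))  # bit-for-bit under a fixed seed

  # identical lists: both at minimum depth, clustered once, ratios 1
  rep3 <- subsample_compare(list(A = b, B = b), replicates = 3, seed = 1)
  expect_equal(glance(rep3)$ratio, c(1, 1))
  expect_equal(unique(tidy(rep3)$n_otus), 5L)

  expect_error(subsample_compare(list(A = b, B = character()), seed = 1),
               class = "overlapfilter_degenerate_input")
})
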