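# Internal helpers shared across modules.

# Deterministically fold a user seed and a few small indices into one 32-bit
# seed, so that per-method / per-replicate random streams are independent of
# how many other methods or replicates exist.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 69069 + as.double(p) + 1) %% 2147483647
  as.integer(s)
}

# Positions (1-based) of every character of `chr` in each string of `x`,
# returned as a logical read_len x n matrix builder used by the simulator.
char_matrix <- function(x, len) {
  stopifnot(all(nchar(x) == len))
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE), nrow = len)
}

collapse_columns <- function(m) {
  apply(m, 2, paste, collapse = "")
}

# sample() that never falls into the 1:n scalar trap
pick <- function(v, n = 1L, replace = FALSE, prob = NULL) {
  v[sample.int(length(v), n, replace = replace, prob = prob)]
}

check_dna <- function(x, alphabet = "ACGTN", arg = "sequence") {
  bad <- stringi::stri_detect_regex(x, sprintf("[^%s]", alphabet))
  if (any(bad)) {
    i <- which(bad)[1]
    abort(
      sprintf("`%s` contains characters outside {%s} (first offender: element %d, \"%s\")",
              arg, paste(strsplit(alphabet, "")[[1]], collapse = ","), i, x[i]),
      class = "overlapfilter_alphabet_error"
    )
  }
  invisible(x)
}
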