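# Shared fixtures, all built in code.

# Four-sample design matching the packaged synthetic design's primers.
test_design <- function() {
  amplicon_design(
    barcodes = c(S1 = "AACTCGTC", S2 = "ACTAGCAG", S3 = "AGTCTGGA", S4 = "ATCGCAAC"),
    proximal_consensus = "CAACGCGMRG",
    distal_primer = "AGGTGGTGCATGGTTGT"
  )
}

# Concrete (non-degenerate) proximal primer, for analytic pass-rate checks.
concrete_design <- function() {
  amplicon_design(
    barcodes = c(S1 = "AACTCGTC", S2 = "ACTAGCAG", S3 = "AGTCTGGA", S4 = "ATCGCAAC"),
    proximal_consensus = "CAACGCGAAG",
    distal_primer = "AGGTGGTGCATGGTTGT"
  )
}

sim_pairs <- function(n, model = error_model(), seed = 1L, design = test_design(),
                      n_templates = 10L, length_range = c(60L, 65L), ...) {
  pool <- generate_templates(n_templates, length_range = length_range,
                             seed = seed, design = design)
  simulate_pairs(pool, design, n, model = model, seed = seed, ...)
}

zero_error_model <- function() {
  error_model(base_error_rate = 0, ramp_slope = 0, n_rate = 0, btail_prob = 0)
}

# Minimal pair tibble for read-level filter tests (both mates explicit).
make_pair_tbl <- function(sequence1, quality1, sequence2 = sequence1,
                          quality2 = quality1) {
  tibble::tibble(sequence1 = sequence1, quality1 = quality1,
                 sequence2 = sequence2, quality2 = quality2)
}

# FASTQ record text for hand-built reads.
fastq_lines <- function(ids, seqs, quals) {
  as.vector(rbind(paste0("@", ids), seqs, "+", quals))
}

random_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
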