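#' Reverse-complement nucleotide sequences
#'
#' Watson-Crick complement, reversed. `N` is its own complement; IUPAC
#' degenerate codes map to their complements (R<->Y, K<->M, B<->V, D<->H,
#' S and W are self-complementary).
#'
#' @param x Character vector over `{A,C,G,T,N}` plus IUPAC codes.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("AANG")  # "CNTT"
#' @export
reverse_complement <- function(x) {
  check_dna(x, "ACGTNRYSWKMBDHV", "sequence")
  stringi::stri_reverse(chartr("ACGTNRYSWKMBDHV", "TGCANYRSWMKVHDB", x))
}

OVERLAP_REASONS <- c("OK", "NO_DISTAL_R1", "NO_DISTAL_R2", "NO_PROXIMAL_R1",
                     "NO_PROXIMAL_R2", "LENGTH_DISAGREEMENT", "MISMATCH", "NO_BARCODE")

# Position-wise mismatch count between equal-length strings; any differing
# position, or any position where either string carries an N, counts. N is
# not a basecall, so two Ns facing each other are still a mismatch.
count_mismatches <- function(a, b) {
  vapply(seq_along(a), function(i) {
    cx <- strsplit(a[i], "", fixed = TRUE)[[1]]
    cy <- strsplit(b[i], "", fixed = TRUE)[[1]]
    sum(cx != cy | cx == "N" | cy == "N")
  }, integer(1))
}

#' Complete-overlap quality filtering of fully overlapping read pairs
#'
#' The core filter. For each pair it (1) reverse-complements read 2;
#' (2) looks for the distal-primer 6-mer within the last 30 nt of read 1 and
#' of the reverse-complemented read 2, failing `NO_DISTAL_R1`/`NO_DISTAL_R2`
#' if either misses; (3) looks for a degenerate match of the proximal
#' consensus 10-mer within the first 40 nt of both, failing
#' `NO_PROXIMAL_R1`/`NO_PROXIMAL_R2`; (4) extracts from each read the region
#' strictly between the matched primers (this removes barcode + proximal
#' primer and the distal primer); (5) requires the two extractions to have
#' equal length (`LENGTH_DISAGREEMENT` otherwise — the comparison is strictly
#' positional, no indel tolerance) and to agree at 100% identity with no N at
#' any position (`MISMATCH` otherwise, with the discordance count recorded);
#' (6) demultiplexes the read-1 barcode prefix (`NO_BARCODE` if no exact
#' match). Only pairs reaching reason `OK` are passed; their retained
#' sequence and qualities are taken from read 1 (the bases are identical
#' between mates at this point by construction).
#'
#' A pair passes only if every inter-primer base was read identically from
#' both strands, so a surviving random sequencing error requires two errors
#' at the same position with complementary base changes — the filter's only
#' blind spot (probability e^2/3 per position at per-read error rate e, see
#' [prob_coincident_error()]).
#'
#' @param pairs A pair tibble ([read_fastq_pairs()] or [simulate_pairs()]).
#' @param design An [amplicon_design()].
#' @return The input tibble plus columns `passed`, `reason` (`OK`,
#'   `NO_DISTAL_R1`, `NO_DISTAL_R2`, `NO_PROXIMAL_R1`, `NO_PROXIMAL_R2`,
#'   `LENGTH_DISAGREEMENT`, `MISMATCH`, `NO_BARCODE`), `sample`,
#'   `n_mismatches`, `has_N`, `trimmed_sequence`, `trimmed_quality`.
#' @export
filter_overlap <- function(pairs, design) {
  n <- nrow(pairs)
  s1 <- pairs$sequence1
  rc2 <- reverse_complement(pairs$sequence2)

  d1 <- find_distal(s1, design)
  d2 <- find_distal(rc2, design)
  p1 <- find_proximal(s1, design)
  p2 <- find_proximal(rc2, design)

  reason <- rep("OK", n)
  # Later assignments win, so order encodes precedence: R1 over R2, distal
  # stage (steps 2-3) over proximal stage (steps 4-5).
  reason[is.na(p2$start)] <- "NO_PROXIMAL_R2"
  reason[is.na(p1$start)] <- "NO_PROXIMAL_R1"
  reason[is.na(d2$start)] <- "NO_DISTAL_R2"
  reason[is.na(d1$start)] <- "NO_DISTAL_R1"

  ok <- reason == "OK"
  v1 <- v2 <- rep(NA_character_, n)
  v1[ok] <- substr(s1[ok], p1$end[ok] + 1L, d1$start[ok] - 1L)
  v2[ok] <- substr(rc2[ok], p2$end[ok] + 1L, d2$start[ok] - 1L)

  reason[ok & nchar(v1) != nchar(v2)] <- "LENGTH_DISAGREEMENT"
  ok <- reason == "OK"

  n_mismatches <- rep(NA_integer_, n)
  clean <- ok & v1 == v2 & !stringi::stri_detect_fixed(v1, "N")
  n_mismatches[clean] <- 0L
  needs_count <- ok & !clean
  n_mismatches[needs_count] <- count_mismatches(v1[needs_count], v2[needs_count])
  reason[needs_count & n_mismatches > 0L] <- "MISMATCH"
  ok <- reason == "OK"

  sample <- rep(NA_character_, n)
  sample[ok] <- demultiplex(s1[ok], p1$start[ok], design)
  reason[ok & is.na(sample)] <- "NO_BARCODE"
  passed <- reason == "OK"

  trimmed_sequence <- trimmed_quality <- rep(NA_character_, n)
  trimmed_sequence[passed] <- v1[passed]
  trimmed_quality[passed] <- substr(pairs$quality1[passed],
                                    p1$end[passed] + 1L, d1$start[passed] - 1L)
  sample[!passed] <- NA_character_

  mutate(pairs,
         passed = passed,
         reason = factor(reason, levels = OVERLAP_REASONS),
         sample = sample,
         n_mismatches = n_mismatches,
         has_N = stringi::stri_detect_fixed(pairs$sequence1, "N") |
                 stringi::stri_detect_fixed(pairs$sequence2, "N"),
         trimmed_sequence = trimmed_sequence,
         trimmed_quality = trimmed_quality)
}

#' Failure ledger: outcome accounting by sample and reason
#'
#' Per-sample, per-reason counts of filter outcomes, with the count of pairs
#' carrying at least one N — the style of accounting used for supplementary
#' failure tables. Reason codes ending `_R1`/`_R2` carry the read direction.
#' Counts partition the input: their sum equals `nrow(result)`.
#'
#' @param result Output of [filter_overlap()] or [filter_qscore()].
#' @param by Optional column name to group by instead of the filter's own
#'   `sample` call (useful with simulator truth).
#' @return A tibble with columns `sample`, `reason`, `direction`, `n`,
#'   `n_with_N`.
#' @export
tally_filter <- function(result, by = NULL) {
  grp <- if (!is.null(by)) {
    result[[by]]
  } else if ("sample" %in% names(result)) {
    result$sample
  } else {
    rep("(all)", nrow(result))
  }
  grp <- ifelse(is.na(grp), "(unassigned)", as.character(grp))
  tibble(sample = grp, reason = as.character(result$reason), has_N = result$has_N) |>
    group_by(.data$sample, .data$reason) |>
    summarise(n = n(), n_with_N = sum(.data$has_N), .groups = "drop") |>
    mutate(direction = dplyr::case_when(
      grepl("_R1$", .data$reason) ~ "R1",
      grepl("_R2$", .data$reason) ~ "R2",
      TRUE ~ NA_character_
    )) |>
    select("sample", "reason", "direction", "n", "n_with_N")
}

#' Write passed, trimmed reads to FASTA or FASTQ
#'
#' @param result Output of [filter_overlap()].
#' @param path Output path.
#' @param format `"fasta"` (default; qualities dropped) or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_passed <- function(result, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  passed <- filter(result, .data$passed)
  ids <- sprintf("%s|sample=%s", passed$id1, passed$sample)
  lines <- if (format == "fasta") {
    as.vector(rbind(paste0(">", ids), passed$trimmed_sequence))
  } else {
    as.vector(rbind(paste0("@", ids), passed$trimmed_sequence, "+", passed$trimmed_quality))
  }
  if (length(lines) == 0L) lines <- character()
  readr::write_lines(lines, path)
  invisible(path)
}

#' Probability arithmetic for coincident undetectable errors
#'
#' With independent substitution errors at per-base rate `e` in each mate
#' (uniform over the three alternative bases), an inter-primer position holds
#' an error that the overlap filter cannot detect only when both mates err
#' *and* the two changes are complementary, i.e. both reads report the same
#' wrong base on the sense strand: probability `e^2 / 3`.
#' `prob_position_concordant()` is the probability that a position survives
#' comparison at all (no error on either mate, or a coincident one).
#'
#' @param e Per-base, per-read substitution error rate.
#' @return A probability.
#' @export
prob_coincident_error <- function(e) e^2 / 3

#' @rdname prob_coincident_error
#' @export
prob_position_concordant <- function(e) (1 - e)^2 + e^2 / 3
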