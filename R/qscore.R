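# Q-score based comparison filters: run-length quality trimming with a
# length-ratio test ("Bokulich"), and B-tail removal with a first-half Q30
# criterion ("Minoche"), applied pair-wise: if either mate fails, the pair
# is discarded.

#' Parameter sets for the Q-score filters
#'
#' Defaults are the published suggested parameters: for the trimming filter
#' `p = 0.75` (minimum trimmed/original length ratio), `q = 3` (a base is
#' low-quality when its score is strictly below `q`), `r = 3` (run length
#' that triggers trimming), `n = 0` (ambiguous bases permitted after
#' trimming). For the B-tail filter `p = 0.75`, B-tail threshold `Q <= 2`
#' (the Illumina 'B' glyph marks Q2), and the "Q33" criterion: at least
#' two-thirds of the bases in the first half of the trimmed read must score
#' strictly above Q30.
#'
#' @param p Minimum trimmed/original length ratio, in `(0, 1]`.
#' @param q,r,n Trimming-filter parameters (see above).
#' @param btail_q Maximum quality of a B-tail base.
#' @param q33_threshold,q33_fraction First-half criterion: require
#'   `> q33_threshold` scores at `>= q33_fraction` of first-half positions.
#' @return A parameter list of class `bokulich_params` / `minoche_params`.
#' @export
bokulich_params <- function(p = 0.75, q = 3L, r = 3L, n = 0L) {
  stopifnot(p > 0, p <= 1, r >= 1, n >= 0)
  structure(list(p = p, q = as.integer(q), r = as.integer(r), n = as.integer(n)),
            class = "bokulich_params")
}

#' @rdname bokulich_params
#' @export
minoche_params <- function(p = 0.75, btail_q = 2L, q33_threshold = 30L,
                           q33_fraction = 2 / 3) {
  stopifnot(p > 0, p <= 1, q33_fraction > 0, q33_fraction <= 1)
  structure(list(p = p, btail_q = as.integer(btail_q),
                 q33_threshold = as.integer(q33_threshold),
                 q33_fraction = q33_fraction),
            class = "minoche_params")
}

# Retained prefix length before the first run of >= r consecutive scores < q.
bokulich_keep_length <- function(quals, q, r) {
  vapply(quals, function(qs) {
    if (!length(qs)) return(0L)
    rl <- rle(qs < q)
    ends <- cumsum(rl$lengths)
    hit <- which(rl$values & rl$lengths >= r)
    if (!length(hit)) length(qs) else as.integer(ends[hit[1]] - rl$lengths[hit[1]])
  }, integer(1))
}

# Retained length after stripping the maximal suffix of scores <= btail_q.
btail_keep_length <- function(quals, btail_q) {
  vapply(quals, function(qs) {
    keep <- which(qs > btail_q)
    if (!length(keep)) 0L else keep[length(keep)]
  }, integer(1))
}

#' Quality-trimming primitives
#'
#' `bokulich_trim()` truncates each read at the first run of at least `r`
#' consecutive bases scoring strictly below `q` (single left-to-right pass,
#' no re-trimming); `btail_trim()` strips the maximal low-quality suffix
#' (scores `<= btail_q`), leaving interior low-quality bases untouched.
#' `minoche_q33()` evaluates the first-half criterion: with
#' `h = floor(length/2)` (at least 1), the read passes when the number of
#' first-half scores strictly above the threshold reaches
#' `ceiling(fraction * h)`; an empty read fails.
#'
#' @param sequence,quality Character vectors (quality as Phred+33 strings).
#' @param q,r,btail_q,threshold,fraction See [bokulich_params()].
#' @return Trimmers: a tibble with trimmed `sequence` and `quality`;
#'   `minoche_q33()`: a logical vector.
#' @export
bokulich_trim <- function(sequence, quality, q = 3L, r = 3L) {
  keep <- bokulich_keep_length(decode_quality(quality), q, r)
  tibble(sequence = substr(sequence, 1L, keep), quality = substr(quality, 1L, keep))
}

#' @rdname bokulich_trim
#' @export
btail_trim <- function(sequence, quality, btail_q = 2L) {
  keep <- btail_keep_length(decode_quality(quality), btail_q)
  tibble(sequence = substr(sequence, 1L, keep), quality = substr(quality, 1L, keep))
}

#' @rdname bokulich_trim
#' @export
minoche_q33 <- function(quality, threshold = 30L, fraction = 2 / 3) {
  vapply(decode_quality(quality), function(qs) {
    if (!length(qs)) return(FALSE)
    h <- max(1L, length(qs) %/% 2L)
    sum(qs[seq_len(h)] > threshold) >= ceiling(fraction * h)
  }, logical(1))
}

# Single-read verdicts. Reason codes: OK, TRIM_LENGTH, AMBIGUOUS, Q33.
qscore_read_verdict <- function(sequence, quality, params) {
  orig_len <- pmax(nchar(sequence), 1L)
  if (inherits(params, "bokulich_params")) {
    keep <- bokulich_keep_length(decode_quality(quality), params$q, params$r)
    trimmed <- substr(sequence, 1L, keep)
    n_amb <- stringi::stri_count_fixed(trimmed, "N")
    reason <- dplyr::case_when(
      keep / orig_len < params$p ~ "TRIM_LENGTH",
      n_amb > params$n ~ "AMBIGUOUS",
      TRUE ~ "OK"
    )
  } else if (inherits(params, "minoche_params")) {
    keep <- btail_keep_length(decode_quality(quality), params$btail_q)
    trimmed <- substr(sequence, 1L, keep)
    q33 <- minoche_q33(substr(quality, 1L, keep),
                       params$q33_threshold, params$q33_fraction)
    reason <- dplyr::case_when(
      keep / orig_len < params$p ~ "TRIM_LENGTH",
      stringi::stri_count_fixed(trimmed, "N") > 0L ~ "AMBIGUOUS",
      !q33 ~ "Q33",
      TRUE ~ "OK"
    )
  } else {
    abort("params must be bokulich_params() or minoche_params()",
          class = "overlapfilter_config_error")
  }
  tibble(pass = reason == "OK", reason = reason, keep = keep,
         trimmed_sequence = substr(sequence, 1L, keep),
         trimmed_quality = substr(quality, 1L, keep))
}

QSCORE_REASONS <- c("OK", "TRIM_LENGTH", "AMBIGUOUS", "Q33", "MATE_FAILED")

#' Pair-level Q-score filtering
#'
#' Applies a Q-score read filter independently to each mate; if either read
#' exhibits low quality by the criteria, both reads are discarded. The pair
#' `reason` is the failing read's reason (read 1 taking precedence);
#' per-read columns additionally tag a read that passed on its own while its
#' mate failed as `MATE_FAILED`.
#'
#' @param pairs A pair tibble.
#' @param method `"bokulich"` or `"minoche"`.
#' @param params Optional [bokulich_params()] / [minoche_params()]; defaults
#'   to the method's published parameters.
#' @return The input tibble plus `passed`, `reason`, `reason1`, `reason2`,
#'   `has_N`, and (on pass) `trimmed_sequence1/2`, `trimmed_quality1/2`.
#' @export
filter_qscore <- function(pairs, method = c("bokulich", "minoche"), params = NULL) {
  method <- match.arg(method)
  params <- params %||% switch(method, bokulich = bokulich_params(), minoche = minoche_params())
  v1 <- qscore_read_verdict(pairs$sequence1, pairs$quality1, params)
  v2 <- qscore_read_verdict(pairs$sequence2, pairs$quality2, params)
  passed <- v1$pass & v2$pass
  reason <- dplyr::case_when(passed ~ "OK", !v1$pass ~ v1$reason, TRUE ~ v2$reason)
  r1 <- ifelse(v1$pass & !v2$pass, "MATE_FAILED", v1$reason)
  r2 <- ifelse(v2$pass & !v1$pass, "MATE_FAILED", v2$reason)
  mutate(pairs,
         passed = passed,
         reason = factor(reason, levels = QSCORE_REASONS),
         reason1 = factor(r1, levels = QSCORE_REASONS),
         reason2 = factor(r2, levels = QSCORE_REASONS),
         has_N = stringi::stri_detect_fixed(pairs$sequence1, "N") |
                 stringi::stri_detect_fixed(pairs$sequence2, "N"),
         trimmed_sequence1 = ifelse(passed, v1$trimmed_sequence, NA_character_),
         trimmed_quality1 = ifelse(passed, v1$trimmed_quality, NA_character_),
         trimmed_sequence2 = ifelse(passed, v2$trimmed_sequence, NA_character_),
         trimmed_quality2 = ifelse(passed, v2$trimmed_quality, NA_character_))
}
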