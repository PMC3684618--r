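#' Decode and encode Phred+33 quality strings
#'
#' CASAVA 1.8+ FASTQ encodes per-base quality as ASCII code point minus 33.
#' Older +64 dialects are deliberately not auto-detected: feeding one in
#' produces implausible scores, not silent misinterpretation.
#'
#' @param x Character vector of quality strings.
#' @param quals List of integer vectors (or a single integer vector), each
#'   value in `[0, 93]`.
#' @return `decode_quality()`: a list of integer vectors, one per input
#'   string. `encode_quality()`: a character vector.
#' @examples
#' decode_quality("#I#")[[1]]   # 2 40 2
#' encode_quality(c(0L, 40L))   # "!I"
#' @export
decode_quality <- function(x) {
  stopifnot(is.character(x))
  lapply(seq_along(x), function(i) {
    cp <- utf8ToInt(x[i])
    bad <- which(cp < 33L | cp > 126L)
    if (length(bad)) {
      abort(
        sprintf("malformed quality string (element %d): code point %d at position %d is outside [33, 126]",
                i, cp[bad[1]], bad[1]),
        class = "overlapfilter_malformed_quality"
      )
    }
    cp - 33L
  })
}

#' @rdname decode_quality
#' @export
encode_quality <- function(quals) {
  if (is.numeric(quals)) quals <- list(as.integer(quals))
  vapply(quals, function(q) {
    stopifnot(all(q >= 0L & q <= 93L))
    intToUtf8(as.integer(q) + 33L)
  }, character(1))
}

#' Parse CASAVA 1.8+ read headers
#'
#' Splits `@instrument:run:flowcell:lane:tile:x:y mate:filtered:control:index`
#' headers into their fields. Parsing is strict: anything that does not have
#' exactly the two space-separated blocks with 7 and 4 colon-delimited fields,
#' numeric coordinates and mate 1/2 raises a malformed-header error.
#'
#' @param line Character vector of header lines (leading `@` required).
#' @return A tibble with columns `instrument`, `run`, `flowcell`, `lane`,
#'   `tile`, `x`, `y`, `mate`, `filtered`, `control`, `index`.
#' @examples
#' parse_casava_header(
#'   "@M00967:43:000000000-A3JHG:1:1101:18327:1699 1:N:0:TCCACAGGAGT")
#' @export
parse_casava_header <- function(line) {
  stopifnot(is.character(line))
  if (length(line) == 0L) {
    return(tibble(instrument = character(), run = integer(), flowcell = character(),
                  lane = integer(), tile = integer(), x = integer(), y = integer(),
                  mate = integer(), filtered = character(), control = integer(),
                  index = character()))
  }
  fail <- function(i, why) {
    abort(sprintf("malformed CASAVA header (record %d): %s: \"%s\"", i, why, line[i]),
          class = "overlapfilter_malformed_header")
  }
  no_at <- which(!startsWith(line, "@"))
  if (length(no_at)) fail(no_at[1], "missing leading '@'")

  halves <- stringi::stri_split_fixed(substring(line, 2L), " ")
  nh <- lengths(halves)
  if (any(nh != 2L)) fail(which(nh != 2L)[1], "expected exactly two space-separated blocks")
  left  <- stringi::stri_split_fixed(vapply(halves, `[`, "", 1L), ":")
  right <- stringi::stri_split_fixed(vapply(halves, `[`, "", 2L), ":")
  if (any(lengths(left) != 7L)) fail(which(lengths(left) != 7L)[1], "coordinate block needs 7 colon-delimited fields")
  if (any(lengths(right) != 4L)) fail(which(lengths(right) != 4L)[1], "member block needs 4 colon-delimited fields")

  lf <- matrix(unlist(left), ncol = 7L, byrow = TRUE)
  rf <- matrix(unlist(right), ncol = 4L, byrow = TRUE)
  num <- function(col, name) {
    v <- suppressWarnings(as.integer(col))
    if (anyNA(v)) fail(which(is.na(v))[1], sprintf("non-numeric %s field", name))
    v
  }
  out <- tibble(
    instrument = lf[, 1], run = num(lf[, 2], "run"), flowcell = lf[, 3],
    lane = num(lf[, 4], "lane"), tile = num(lf[, 5], "tile"),
    x = num(lf[, 6], "x"), y = num(lf[, 7], "y"),
    mate = num(rf[, 1], "mate"), filtered = rf[, 2],
    control = num(rf[, 3], "control"), index = rf[, 4]
  )
  if (any(!out$mate %in% c(1L, 2L))) fail(which(!out$mate %in% c(1L, 2L))[1], "mate must be 1 or 2")
  if (any(!out$filtered %in% c("Y", "N"))) fail(which(!out$filtered %in% c("Y", "N"))[1], "filtered flag must be Y or N")
  out
}

format_casava_header <- function(reads) {
  sprintf("@%s:%d:%s:%d:%d:%d:%d %d:%s:%d:%s",
          reads$instrument, reads$run, reads$flowcell, reads$lane, reads$tile,
          reads$x, reads$y, reads$mate, reads$filtered, reads$control, reads$index)
}

#' Read and write FASTQ files (CASAVA 1.8+ dialect)
#'
#' `read_fastq()` loads a 4-line-record FASTQ file (plain or gzip) into a
#' tibble with one row per read: the raw header (`id`, without `@`), the
#' parsed header fields, `sequence` and `quality` (Phred+33 string).
#' `write_fastq()` is its inverse; a read-write-read round trip is
#' byte-identical.
#'
#' @param path File path; `.gz` handled transparently.
#' @param reads A tibble as returned by `read_fastq()`.
#' @return A tibble of reads; `write_fastq()` returns `path` invisibly.
#' @export
read_fastq <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  if (length(lines) %% 4L != 0L) {
    abort(sprintf("truncated FASTQ: %s has %d lines, not a multiple of 4", path, length(lines)),
          class = "overlapfilter_truncated_input")
  }
  n <- length(lines) %/% 4L
  if (n == 0L) {
    return(bind_cols(tibble(id = character()),
                     parse_casava_header(character()),
                     tibble(sequence = character(), quality = character())))
  }
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  if (any(!startsWith(plus, "+"))) {
    abort(sprintf("malformed FASTQ record %d in %s: third line does not start with '+'",
                  which(!startsWith(plus, "+"))[1], path),
          class = "overlapfilter_malformed_record")
  }
  if (any(nchar(seqs) != nchar(qual))) {
    abort(sprintf("malformed FASTQ record %d in %s: sequence and quality lengths differ",
                  which(nchar(seqs) != nchar(qual))[1], path),
          class = "overlapfilter_malformed_record")
  }
  check_dna(seqs)
  bind_cols(tibble(id = substring(hdr, 2L)), parse_casava_header(hdr),
            tibble(sequence = seqs, quality = qual))
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  lines <- as.vector(rbind(paste0("@", reads$id), reads$sequence, "+", reads$quality))
  if (length(lines) == 0L) lines <- character()
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read position-synchronized paired FASTQ files
#'
#' Loads both mates and pairs them record by record, enforcing the pairing
#' contract: equal record counts, mate fields 1/2, and identical flow-cell
#' coordinates (`instrument`, `run`, `flowcell`, `lane`, `tile`, `x`, `y`).
#' The first violating record is named in the error.
#'
#' @param path1,path2 FASTQ paths for read 1 and read 2.
#' @return A pair tibble with one row per pair: shared coordinate columns,
#'   `id1`, `id2`, `sequence1`, `quality1`, `sequence2`, `quality2`,
#'   `filtered1`, `filtered2`, `index`.
#' @export
read_fastq_pairs <- function(path1, path2) {
  r1 <- read_fastq(path1)
  r2 <- read_fastq(path2)
  pair_reads(r1, r2)
}

#' @rdname read_fastq_pairs
#' @param r1,r2 Read tibbles from [read_fastq()].
#' @export
pair_reads <- function(r1, r2) {
  if (nrow(r1) != nrow(r2)) {
    abort(sprintf("truncated input: %d read-1 records but %d read-2 records (pairing stops after pair %d)",
                  nrow(r1), nrow(r2), min(nrow(r1), nrow(r2))),
          class = "overlapfilter_truncated_input")
  }
  if (nrow(r1) && any(r1$mate != 1L)) {
    abort(sprintf("pairing error: record %d of the first file has mate=%d, expected 1",
                  which(r1$mate != 1L)[1], r1$mate[which(r1$mate != 1L)[1]]),
          class = "overlapfilter_pairing_error")
  }
  if (nrow(r2) && any(r2$mate != 2L)) {
    abort(sprintf("pairing error: record %d of the second file has mate=%d, expected 2",
                  which(r2$mate != 2L)[1], r2$mate[which(r2$mate != 2L)[1]]),
          class = "overlapfilter_pairing_error")
  }
  coord <- c("instrument", "run", "flowcell", "lane", "tile", "x", "y")
  mism <- which(Reduce(`|`, lapply(coord, function(k) r1[[k]] != r2[[k]])))
  if (length(mism)) {
    abort(sprintf("pairing error: coordinate mismatch at record %d (\"%s\" vs \"%s\")",
                  mism[1], r1$id[mism[1]], r2$id[mism[1]]),
          class = "overlapfilter_pairing_error")
  }
  bind_cols(
    r1[coord],
    tibble(id1 = r1$id, id2 = r2$id,
           sequence1 = r1$sequence, quality1 = r1$quality,
           sequence2 = r2$sequence, quality2 = r2$quality,
           filtered1 = r1$filtered, filtered2 = r2$filtered,
           control1 = r1$control, control2 = r2$control,
           index = r1$index)
  )
}

#' Split a pair tibble back into per-mate read tibbles
#'
#' @param pairs A pair tibble (see [read_fastq_pairs()]).
#' @param mate 1 or 2.
#' @return A read tibble suitable for [write_fastq()].
#' @export
pairs_to_reads <- function(pairs, mate = 1L) {
  stopifnot(mate %in% c(1L, 2L))
  m <- if (mate == 1L) "1" else "2"
  tibble(
    id = pairs[[paste0("id", m)]],
    instrument = pairs$instrument, run = pairs$run, flowcell = pairs$flowcell,
    lane = pairs$lane, tile = pairs$tile, x = pairs$x, y = pairs$y,
    mate = as.integer(mate), filtered = pairs[[paste0("filtered", m)]],
    control = pairs[[paste0("control", m)]], index = pairs$index,
    sequence = pairs[[paste0("sequence", m)]],
    quality = pairs[[paste0("quality", m)]]
  )
}
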