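# Amplicon design: fusion-primer construct model, degenerate primer matching
# and inline-barcode demultiplexing.

IUPAC_SETS <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

# Regex character class for one IUPAC code. N in the *read* never matches any
# pattern position (no evidence of identity), which falls out naturally here
# because no class contains the letter N.
iupac_regex <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(IUPAC_SETS))
  if (length(bad)) {
    abort(sprintf("invalid IUPAC code \"%s\" at position %d of pattern \"%s\"",
                  chars[bad[1]], bad[1], pattern),
          class = "overlapfilter_config_error")
  }
  paste0("[", IUPAC_SETS[chars], "]", collapse = "")
}

# All concrete A/C/G/T expansions of a degenerate pattern.
iupac_expand <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  sets <- strsplit(IUPAC_SETS[chars], "", fixed = TRUE)
  do.call(paste0, rev(expand.grid(rev(sets), stringsAsFactors = FALSE)))
}

#' Describe an amplicon design: barcodes, primers and search windows
#'
#' Models the fusion-primer construct of a fully overlapping amplicon library:
#' an inline 5' barcode on read 1, a (possibly degenerate) proximal primer
#' whose first 10 nt anchor the start of the biological region, and a distal
#' primer whose first 6 nt anchor its end. The proximal 10-mer is searched
#' within the first `proximal_window` (default 40) nt of a read, the distal
#' 6-mer within the last `distal_window` (default 30) nt.
#'
#' @param barcodes Named character vector: names are sample labels, values are
#'   A/C/G/T barcode sequences (lengths may differ; all values distinct).
#' @param proximal_consensus Degenerate IUPAC string, length >= 10. Only the
#'   first 10 nt are used for matching; if longer, the tail is *retained* in
#'   the trimmed output (trim coordinates anchor at the matched 10-mer).
#' @param distal_primer A/C/G/T-initial string, length >= 6; the first 6 nt
#'   (which must be non-degenerate) are matched exactly.
#' @param proximal_window,distal_window Search-window sizes in nt.
#' @return An `amplicon_design` object.
#' @examples
#' amplicon_design(c(S1 = "ACGTACGT"), "CAACGCGMRG", "AGGTGGTGCATGGTTGT")
#' @export
amplicon_design <- function(barcodes, proximal_consensus, distal_primer,
                            proximal_window = 40L, distal_window = 30L) {
  if (is.data.frame(barcodes)) {
    stopifnot(all(c("sample", "barcode") %in% names(barcodes)))
    barcodes <- stats::setNames(barcodes$barcode, barcodes$sample)
  }
  if (is.null(names(barcodes)) || any(names(barcodes) == "")) {
    abort("barcodes must be a named vector (names are sample labels)",
          class = "overlapfilter_config_error")
  }
  if (anyDuplicated(barcodes)) {
    abort(sprintf("duplicated barcode \"%s\": two samples would demultiplex identically",
                  barcodes[duplicated(barcodes)][1]),
          class = "overlapfilter_config_error")
  }
  if (anyDuplicated(names(barcodes))) {
    abort("duplicated sample labels in barcode table", class = "overlapfilter_config_error")
  }
  check_dna(barcodes, "ACGT", "barcodes")
  if (nchar(proximal_consensus) < 10L) {
    abort("proximal_consensus must be at least 10 nt", class = "overlapfilter_config_error")
  }
  if (nchar(distal_primer) < 6L) {
    abort("distal_primer must be at least 6 nt", class = "overlapfilter_config_error")
  }
  check_dna(substr(distal_primer, 1L, 6L), "ACGT", "distal_primer[1:6]")
  prox10 <- substr(proximal_consensus, 1L, 10L)
  design <- structure(
    list(
      barcodes = barcodes,
      proximal_consensus = proximal_consensus,
      distal_primer = distal_primer,
      proximal_window = as.integer(proximal_window),
      distal_window = as.integer(distal_window),
      prox10 = prox10,
      prox10_regex = iupac_regex(prox10),
      consensus_regex = iupac_regex(proximal_consensus),
      distal6 = substr(distal_primer, 1L, 6L)
    ),
    class = "amplicon_design"
  )
  design
}

#' @export
print.amplicon_design <- function(x, ...) {
  cat("<amplicon_design>\n")
  cat(sprintf("  %d barcodes (%s)\n", length(x$barcodes),
              paste(head(names(x$barcodes), 4), collapse = ", ")))
  cat(sprintf("  proximal consensus: %s (match on first 10 nt, window %d)\n",
              x$proximal_consensus, x$proximal_window))
  cat(sprintf("  distal primer:      %s (match on first 6 nt, window %d)\n",
              x$distal_primer, x$distal_window))
  invisible(x)
}

#' Read and write design files
#'
#' Plain tab-separated key-value format: one `proximal_consensus` line, one
#' `distal_primer` line, optional `proximal_window` / `distal_window` lines,
#' and one `barcode <sample> <sequence>` line per sample. Lines starting with
#' `#` are comments. The file is validated on load.
#'
#' @param path Design file path.
#' @param design An `amplicon_design`.
#' @return `read_design()`: an `amplicon_design`; `write_design()`: `path`,
#'   invisibly.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("design file not found: %s", path), class = "overlapfilter_config_error")
  }
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  key <- vapply(fields, `[`, "", 1L)
  get1 <- function(k, default = NULL) {
    i <- which(key == k)
    if (!length(i)) {
      if (!is.null(default)) return(default)
      abort(sprintf("design file %s is missing a \"%s\" line", path, k),
            class = "overlapfilter_config_error")
    }
    fields[[i[1]]][2]
  }
  bc <- which(key == "barcode")
  if (!length(bc)) {
    abort(sprintf("design file %s declares no barcodes", path),
          class = "overlapfilter_config_error")
  }
  barcodes <- stats::setNames(
    vapply(fields[bc], `[`, "", 3L),
    vapply(fields[bc], `[`, "", 2L)
  )
  amplicon_design(
    barcodes = barcodes,
    proximal_consensus = get1("proximal_consensus"),
    distal_primer = get1("distal_primer"),
    proximal_window = as.integer(get1("proximal_window", "40")),
    distal_window = as.integer(get1("distal_window", "30"))
  )
}

#' @rdname read_design
#' @export
write_design <- function(design, path) {
  lines <- c(
    paste0("proximal_consensus\t", design$proximal_consensus),
    paste0("distal_primer\t", design$distal_primer),
    paste0("proximal_window\t", design$proximal_window),
    paste0("distal_window\t", design$distal_window),
    paste0("barcode\t", names(design$barcodes), "\t", design$barcodes)
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' The packaged synthetic example design
#'
#' A self-consistent stand-in for a real V6 design: 12 inline 8-nt barcodes,
#' a degenerate 10-nt proximal consensus with exactly four concrete
#' expansions (mirroring a four-primer proximal cocktail) and a 17-nt distal
#' primer. The sequences are synthetic; for real data supply your own design
#' file with the primers actually used.
#'
#' @return An `amplicon_design`.
#' @export
example_design <- function() {
  read_design(system.file("extdata", "design_synthetic.tsv",
                          package = "overlapfilter", mustWork = TRUE))
}

#' Find all degenerate-pattern matches in a sequence window
#'
#' Every start position (1-based) at which each window base lies in the IUPAC
#' expansion of the corresponding pattern base. An N in the window matches no
#' pattern position, degenerate or otherwise: N carries no evidence of
#' identity.
#'
#' @param pattern IUPAC degenerate string.
#' @param window A/C/G/T/N subject string.
#' @return Integer vector of match starts (possibly empty); overlapping
#'   matches are all reported.
#' @examples
#' degenerate_match("AR", "AAAG")  # 1 3
#' @export
degenerate_match <- function(pattern, window) {
  check_dna(window, "ACGTN", "window")
  rx <- paste0("(?=", iupac_regex(pattern), ")")
  m <- gregexpr(rx, window, perl = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m)
}

#' Locate the distal and proximal primer anchors in reads
#'
#' `find_distal()` searches for the exact first 6 nt of the distal primer
#' within the last `distal_window` nt of each read (the match must *start*
#' inside the window); `find_proximal()` searches for a degenerate match of
#' the first 10 nt of the proximal consensus starting within the first
#' `proximal_window` nt. Both take the leftmost occurrence inside their
#' window — a deterministic tie-break that maximises the retained region.
#'
#' @param sequences Character vector of reads (A/C/G/T/N).
#' @param design An [amplicon_design()].
#' @return A tibble with columns `start` and `end` (1-based, inclusive; `NA`
#'   where there is no in-window match).
#' @export
find_distal <- function(sequences, design) {
  len <- nchar(sequences)
  wstart <- pmax(1L, len - design$distal_window + 1L)
  loc <- stringi::stri_locate_first_fixed(substr(sequences, wstart, len), design$distal6)[, 1]
  start <- wstart + loc - 1L
  tibble(start = as.integer(start), end = as.integer(start + 5L))
}

#' @rdname find_distal
#' @export
find_proximal <- function(sequences, design) {
  len <- nchar(sequences)
  # Search space: a start within the window may extend up to 9 nt beyond it.
  sub <- substr(sequences, 1L, pmin(len, design$proximal_window + 9L))
  loc <- stringi::stri_locate_first_regex(sub, design$prox10_regex)[, 1]
  loc[!is.na(loc) & loc > design$proximal_window] <- NA_integer_
  tibble(start = as.integer(loc), end = as.integer(loc + 9L))
}

#' Demultiplex reads by exact inline-barcode prefix
#'
#' The subsequence of read 1 strictly before the proximal-primer hit is
#' compared for exact equality against every configured barcode; no
#' mismatches are tolerated (no error-tolerant barcode recovery is reported
#' for this protocol). Barcode lengths may differ because the comparison is
#' keyed off the primer position, not a fixed offset.
#'
#' @param sequences Read-1 sequences.
#' @param proximal_start 1-based start of the proximal hit in each read
#'   (e.g. `find_proximal(...)$start`).
#' @param design An [amplicon_design()].
#' @return Character vector of sample labels (`NA` where no barcode matches).
#' @export
demultiplex <- function(sequences, proximal_start, design) {
  prefix <- rep(NA_character_, length(sequences))
  ok <- !is.na(proximal_start)
  prefix[ok] <- substr(sequences[ok], 1L, proximal_start[ok] - 1L)
  names(design$barcodes)[match(prefix, design$barcodes)]
}
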