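# Synthetic paired-end amplicon read simulator. Generates fully overlapping
# V6-style read pairs with controlled error structure and writes ground truth
# alongside, so every filter and the comparison protocol are testable without
# external data. All randomness flows from explicit seeds.

#' Simulator error model
#'
#' Per-base substitution errors at rate `base_error_rate + ramp_slope *
#' (cycle - 1)` (capped at 0.75), uniform over the three alternative bases;
#' independent N calls at `n_rate`; optional B-tails (a Q2 suffix of random
#' length) on read 2 at `btail_prob`; and optional cycle-specific systematic
#' miscall hotspots: `n_hotspots` fixed read-1 cycles at which, with
#' probability `hotspot_rate` per read, the base is replaced by a fixed
#' per-hotspot target base. Hotspots model the reproducible cycle- and
#' context-specific miscalls of real Illumina runs — errors that recur at
#' the same position with the same substitution across reads, receive high
#' quality scores, and are exactly what makes Q-score-only filtering
#' over-optimistic.
#'
#' Reported qualities: when `miscalibration = FALSE`, Q is the Phred
#' transform of the position's modelled error probability (capped at 40), so
#' Q-score filters behave sensibly. When `TRUE`, Q is drawn from a high-Q
#' distribution (36-40, mean ~38) independently of the true error process.
#'
#' @param base_error_rate,ramp_slope,n_rate,btail_prob Probabilities.
#' @param btail_length_range Integer `(min, max)` B-tail length.
#' @param miscalibration Draw reported Q independently of the error process?
#' @param n_hotspots,hotspot_rate,hotspot_mate Systematic miscall hotspots
#'   (0 = off; applied to `"r1"`, `"r2"` or `"both"`).
#' @return An `error_model` object.
#' @export
error_model <- function(base_error_rate = 0.001, ramp_slope = 5e-5,
                        n_rate = 5e-4, btail_prob = 0.05,
                        btail_length_range = c(5L, 25L),
                        miscalibration = FALSE,
                        n_hotspots = 0L, hotspot_rate = 0.3,
                        hotspot_mate = c("r1", "r2", "both")) {
  probs <- c(base_error_rate, n_rate, btail_prob, hotspot_rate)
  stopifnot(all(probs >= 0), all(probs <= 1), ramp_slope >= 0,
            length(btail_length_range) == 2L,
            btail_length_range[1] >= 1L,
            btail_length_range[2] >= btail_length_range[1])
  structure(
    list(base_error_rate = base_error_rate, ramp_slope = ramp_slope,
         n_rate = n_rate, btail_prob = btail_prob,
         btail_length_range = as.integer(btail_length_range),
         miscalibration = isTRUE(miscalibration),
         n_hotspots = as.integer(n_hotspots), hotspot_rate = hotspot_rate,
         hotspot_mate = match.arg(hotspot_mate)),
    class = "error_model"
  )
}

#' The miscalibrated-run study condition
#'
#' The error model used throughout this package to emulate a run whose
#' reported quality scores overstate basecall accuracy: a 1% flat
#' substitution rate and three read-1 miscall hotspots firing in 30% of
#' reads, while reported scores sit at Q36-40 (mean ~38). Under this model
#' Q-score filters accept nearly everything, the overlap filter rejects the
#' error-bearing pairs, and recurring hotspot miscalls form spurious OTUs —
#' the qualitative behaviour of a miscalibrated sequencing run.
#'
#' @return An `error_model`.
#' @export
scenario_miscalibrated <- function() {
  error_model(base_error_rate = 0.01, ramp_slope = 0, n_rate = 0.001,
              btail_prob = 0.05, miscalibration = TRUE,
              n_hotspots = 3L, hotspot_rate = 0.3, hotspot_mate = "r1")
}

# TRUE when a template can sit between the primers without creating a
# spurious in-window distal anchor: the distal 6-mer must occur in
# template + distal only at the true junction position. (Biologically,
# primer sites are conserved flanks, not inter-primer sequence.)
template_clean <- function(template, design) {
  vapply(template, function(tpl) {
    s <- paste0(tpl, design$distal6)
    hits <- stringi::stri_locate_all_fixed(s, design$distal6, overlap = TRUE)[[1]][, 1]
    identical(as.integer(hits), nchar(tpl) + 1L)
  }, logical(1), USE.NAMES = FALSE)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Generate a pool of related template sequences
#'
#' One random ancestor plus `n - 1` derived templates, each differing from
#' the ancestor by `ceiling(divergence * length)` substitutions (at least 1)
#' at random positions, with log-series-like abundances (Fisher log series,
#' `w_k` proportional to `0.9^k / k`) — the skewed abundance structure
#' typical of amplicon communities. When a `design` is supplied, templates
#' are rejection-sampled so the distal anchor occurs only at its true
#' position in the assembled construct (see the methods vignette).
#'
#' @param n Number of templates.
#' @param length_range Integer `(min, max)` template length.
#' @param divergence Per-template substitution fraction from the ancestor.
#' @param seed Integer seed.
#' @param design Optional [amplicon_design()] to screen templates against.
#' @return A `template_pool`: list with `templates` (character) and
#'   `abundance` (numeric weights).
#' @export
generate_templates <- function(n, length_range = c(60L, 65L), divergence = 0.05,
                               seed, design = NULL) {
  stopifnot(n >= 1L, length(length_range) == 2L, divergence >= 0, divergence <= 1)
  withr::with_seed(derive_seed(seed, 101L), {
    draw_clean <- function(len) {
      for (i in seq_len(200L)) {
        tpl <- random_dna(1L, len)
        if (is.null(design) || template_clean(tpl, design)) return(tpl)
      }
      abort("could not draw a template free of internal primer motifs",
            class = "overlapfilter_config_error")
    }
    len <- pick(seq(length_range[1], length_range[2]))
    ancestor <- draw_clean(len)
    templates <- ancestor
    if (n > 1L) {
      k <- max(1L, ceiling(divergence * len))
      bases <- c("A", "C", "G", "T")
      for (j in seq_len(n - 1L)) {
        for (try in seq_len(200L)) {
          chars <- strsplit(ancestor, "", fixed = TRUE)[[1]]
          pos <- sample(len, k)
          chars[pos] <- vapply(chars[pos],
                               function(b) pick(setdiff(bases, b)),
                               character(1))
          tpl <- paste(chars, collapse = "")
          if ((is.null(design) || template_clean(tpl, design)) &&
              !tpl %in% templates) break
          tpl <- NULL
        }
        if (is.null(tpl)) {
          abort("could not derive a distinct, primer-motif-free template",
                class = "overlapfilter_config_error")
        }
        templates <- c(templates, tpl)
      }
    }
    k <- seq_len(n)
    structure(list(templates = templates, abundance = 0.9^k / k),
              class = "template_pool")
  })
}

#' @export
print.template_pool <- function(x, ...) {
  cat(sprintf("<template_pool> %d templates, lengths %d-%d\n",
              length(x$templates), min(nchar(x$templates)), max(nchar(x$templates))))
  invisible(x)
}

SIM_BASES <- c("A", "C", "G", "T")
# Row i: the three substitution alternatives for base i.
SIM_OTHERS <- rbind(c("C", "G", "T"), c("A", "G", "T"),
                    c("A", "C", "T"), c("A", "C", "G"))

#' Simulate fully overlapping paired-end amplicon reads
#'
#' Assembles, per pair, the construct `barcode + proximal-primer realization
#' (a concrete expansion of the degenerate consensus) + template + distal
#' primer + adaptor`, reads `read_len` nt from each end (read 2 is the
#' reverse complement of the construct's tail) and applies the error model
#' independently to each mate. The pair of each construct must fully span
#' it: construct length may exceed `read_len` by at most the barcode length,
#' otherwise a configuration error is raised. Constructs whose error-free
#' reads would not anchor both primers at their true positions (a spurious
#' primer motif straddling a junction) are redrawn, so zero-error pairs
#' always pass the overlap filter by construction.
#'
#' Ground truth is carried in extra columns; tests never re-infer truth from
#' the sequences. `insert` is the true retained (inter-primer) region;
#' `n_v6_err1`/`n_v6_err2` count injected discrepancies (substitutions or N
#' calls) inside it, in read 1 and read 2.
#'
#' @param pool A [generate_templates()] pool.
#' @param design An [amplicon_design()].
#' @param n_pairs Number of pairs.
#' @param model An [error_model()].
#' @param seed Integer seed.
#' @param read_len Read length in cycles (default 101).
#' @param adaptor Downstream adaptor padding appended after the distal
#'   primer (may be `""`).
#' @return A pair tibble (same schema as [read_fastq_pairs()]) with
#'   additional truth columns `template_id`, `truth_sample`, `barcode`,
#'   `construct_len`, `v6_start1`, `v6_end1`, `v6_start2_rc`, `v6_end2_rc`,
#'   `insert`, `n_err1`, `n_err2`, `n_v6_err1`, `n_v6_err2`, `n_N1`, `n_N2`.
#' @export
simulate_pairs <- function(pool, design, n_pairs, model = error_model(), seed,
                           read_len = 101L, adaptor = "AGATCGGA") {
  stopifnot(inherits(pool, "template_pool"), inherits(design, "amplicon_design"),
            n_pairs >= 1L)
  read_len <- as.integer(read_len)
  withr::with_seed(derive_seed(seed, 202L), {
    n_tpl <- length(pool$templates)
    samples <- rep_len(names(design$barcodes), n_pairs)
    barcode <- unname(design$barcodes[samples])
    bclen <- nchar(barcode)

    # Proximal realizations: concrete expansions of the degenerate consensus,
    # screened per barcode so no spurious degenerate match starts inside the
    # barcode at the barcode/primer junction.
    exps <- iupac_expand(design$proximal_consensus)
    valid <- lapply(design$barcodes, function(b) {
      ok <- vapply(exps, function(e) {
        starts <- degenerate_match(design$prox10, paste0(b, e))
        !any(starts < nchar(b) + 1L)
      }, logical(1), USE.NAMES = FALSE)
      which(ok)
    })
    if (any(lengths(valid) == 0L)) {
      abort(sprintf("barcode \"%s\" always creates a spurious proximal match at the junction; choose different barcodes",
                    design$barcodes[lengths(valid) == 0L][1]),
            class = "overlapfilter_config_error")
    }

    draw_realization <- function(samples) {
      idx <- integer(length(samples))
      for (s in unique(samples)) {
        i <- which(samples == s)
        v <- valid[[s]]
        idx[i] <- v[sample.int(length(v), length(i), replace = TRUE)]
      }
      exps[idx]
    }

    tidx <- sample.int(n_tpl, n_pairs, replace = TRUE, prob = pool$abundance)
    realization <- draw_realization(samples)

    assemble <- function(tidx, realization) {
      paste0(barcode, realization, pool$templates[tidx], design$distal_primer, adaptor)
    }
    # Geometry: both mates must fully span any construct this pool/design can
    # produce, i.e. read_len <= L <= read_len + barcode length per barcode.
    fixed_len <- nchar(exps[1]) + nchar(design$distal_primer) + nchar(adaptor)
    trange <- range(nchar(pool$templates))
    for (b in design$barcodes) {
      Lr <- nchar(b) + fixed_len + trange
      if (Lr[1] < read_len || Lr[2] - read_len > nchar(b)) {
        abort(sprintf(paste0("construct geometry not coverable for barcode \"%s\": lengths %d-%d ",
                             "must lie in [read_len, read_len + barcode length] = [%d, %d]; ",
                             "adjust template lengths or adaptor padding"),
                      b, Lr[1], Lr[2], read_len, read_len + nchar(b)),
              class = "overlapfilter_config_error")
      }
    }
    construct <- assemble(tidx, realization)
    L <- nchar(construct)

    nc <- nchar(realization)
    expect_prox <- bclen + 1L
    expect_dist <- bclen + nc + nchar(pool$templates[tidx]) + 1L
    offset <- L - read_len

    construct_ok <- function(construct) {
      r1c <- substr(construct, 1L, read_len)
      rc2c <- substr(construct, offset + 1L, L)
      p1 <- find_proximal(r1c, design)$start
      d1 <- find_distal(r1c, design)$start
      p2 <- find_proximal(rc2c, design)$start
      d2 <- find_distal(rc2c, design)$start
      !is.na(p1) & !is.na(d1) & !is.na(p2) & !is.na(d2) &
        p1 == expect_prox & d1 == expect_dist &
        p2 == expect_prox - offset & d2 == expect_dist - offset
    }

    ok <- construct_ok(construct)
    for (round in seq_len(30L)) {
      if (all(ok)) break
      bad <- which(!ok)
      tidx[bad] <- sample.int(n_tpl, length(bad), replace = TRUE, prob = pool$abundance)
      realization[bad] <- draw_realization(samples[bad])
      construct[bad] <- assemble(tidx[bad], realization[bad])
      L <- nchar(construct)
      offset <- L - read_len
      expect_dist <- bclen + nchar(realization) + nchar(pool$templates[tidx]) + 1L
      ok <- construct_ok(construct)
    }
    if (!all(ok)) {
      abort("could not assemble constructs whose clean reads anchor both primers; screen the template pool against this design",
            class = "overlapfilter_config_error")
    }
    nc <- nchar(realization)

    r1_clean <- substr(construct, 1L, read_len)
    rc2_clean <- substr(construct, offset + 1L, L)
    r2_clean <- reverse_complement(rc2_clean)

    m1 <- clean1 <- char_matrix(r1_clean, read_len)
    m2 <- clean2 <- char_matrix(r2_clean, read_len)

    p_pos <- pmin(model$base_error_rate + model$ramp_slope * (seq_len(read_len) - 1L), 0.75)
    substitute_errors <- function(m) {
      hit <- which(matrix(runif(read_len * n_pairs), read_len) < p_pos)
      if (length(hit)) {
        cur <- match(m[hit], SIM_BASES)
        m[hit] <- SIM_OTHERS[cbind(cur, sample.int(3L, length(hit), replace = TRUE))]
      }
      m
    }
    m1 <- substitute_errors(m1)
    m2 <- substitute_errors(m2)

    if (model$n_hotspots > 0L) {
      lo <- max(25L, max(bclen + nc) + 1L)
      hi <- min(70L, min(expect_dist) - 1L)
      stopifnot(hi > lo)
      cycles <- pick(seq(lo, hi), model$n_hotspots)
      targets <- pick(SIM_BASES, model$n_hotspots, replace = TRUE)
      for (k in seq_len(model$n_hotspots)) {
        fired <- runif(n_pairs) < model$hotspot_rate
        if (model$hotspot_mate %in% c("r1", "both")) m1[cycles[k], fired] <- targets[k]
        if (model$hotspot_mate %in% c("r2", "both")) m2[cycles[k], fired] <- targets[k]
      }
    }

    if (model$n_rate > 0) {
      m1[matrix(runif(read_len * n_pairs), read_len) < model$n_rate] <- "N"
      m2[matrix(runif(read_len * n_pairs), read_len) < model$n_rate] <- "N"
    }

    v6_start1 <- bclen + nc + 1L
    v6_end1 <- expect_dist - 1L
    v6_start2_rc <- v6_start1 - offset
    v6_end2_rc <- v6_end1 - offset

    rowidx <- matrix(seq_len(read_len), read_len, n_pairs)
    in_range <- function(lo, hi) {
      sweep(rowidx, 2L, lo, ">=") & sweep(rowidx, 2L, hi, "<=")
    }
    neq1 <- m1 != clean1
    neq2 <- m2 != clean2
    # v6 range in read-2 coordinates (read 2 runs 3'->5' along the construct)
    v6_start2_read <- read_len + 1L - v6_end2_rc
    v6_end2_read <- read_len + 1L - v6_start2_rc

    # Reported qualities
    if (model$miscalibration) {
      draw_q <- function() {
        qm <- matrix(sample(c(36L, 37L, 38L, 39L, 40L), read_len * n_pairs,
                            replace = TRUE, prob = c(0.1, 0.2, 0.4, 0.2, 0.1)),
                     read_len)
        apply(qm + 33L, 2L, intToUtf8)
      }
      q1 <- draw_q()
      q2 <- draw_q()
    } else {
      p_tot <- pmin(p_pos + model$n_rate, 0.999)
      qv <- pmin(40L, as.integer(round(-10 * log10(pmax(p_tot, 1e-10)))))
      qstr <- intToUtf8(qv + 33L)
      q1 <- rep(qstr, n_pairs)
      q2 <- rep(qstr, n_pairs)
    }
    if (model$btail_prob > 0) {
      fired <- which(runif(n_pairs) < model$btail_prob)
      if (length(fired)) {
        lens <- pick(seq(model$btail_length_range[1], model$btail_length_range[2]),
                     length(fired), replace = TRUE)
        stringi::stri_sub(q2[fired], read_len - lens + 1L, read_len) <-
          strrep("#", lens)  # '#' = Phred 2, the B-tail glyph's modern equivalent
      }
    }

    ids <- sprintf("SIM001:1:SIMFC1:1:1101:%d:%d", seq_len(n_pairs), 1L)
    tibble(
      instrument = "SIM001", run = 1L, flowcell = "SIMFC1", lane = 1L,
      tile = 1101L, x = seq_len(n_pairs), y = 1L,
      id1 = paste0(ids, " 1:N:0:ACGTACGT"),
      id2 = paste0(ids, " 2:N:0:ACGTACGT"),
      sequence1 = collapse_columns(m1), quality1 = q1,
      sequence2 = collapse_columns(m2), quality2 = q2,
      filtered1 = "N", filtered2 = "N", control1 = 0L, control2 = 0L,
      index = "ACGTACGT",
      template_id = tidx, truth_sample = samples, barcode = barcode,
      construct_len = L,
      v6_start1 = v6_start1, v6_end1 = v6_end1,
      v6_start2_rc = v6_start2_rc, v6_end2_rc = v6_end2_rc,
      insert = substr(construct, v6_start1, v6_end1),
      n_err1 = colSums(neq1), n_err2 = colSums(neq2),
      n_v6_err1 = colSums(neq1 & in_range(v6_start1, v6_end1)),
      n_v6_err2 = colSums(neq2 & in_range(v6_start2_read, v6_end2_read)),
      n_N1 = colSums(m1 == "N"), n_N2 = colSums(m2 == "N")
    )
  })
}

#' Simulate a run and write paired FASTQ plus a truth table
#'
#' Templates are drawn by abundance and barcodes round-robin across the
#' configured samples; two position-synchronized FASTQ files and a
#' tab-separated truth table (pair id, template, sample, error accounting)
#' are written. Byte-identical across re-runs with the same seed.
#'
#' @inheritParams simulate_pairs
#' @param dir Output directory (created if needed).
#' @param gzip Compress the FASTQ files?
#' @return Invisibly, a list with `r1`, `r2`, `truth` paths and the pair
#'   tibble (`pairs`).
#' @export
simulate_run <- function(pool, design, n_pairs, model = error_model(), seed,
                         dir, read_len = 101L, adaptor = "AGATCGGA", gzip = FALSE) {
  pairs <- simulate_pairs(pool, design, n_pairs, model, seed,
                          read_len = read_len, adaptor = adaptor)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  r1_path <- file.path(dir, paste0("r1", ext))
  r2_path <- file.path(dir, paste0("r2", ext))
  truth_path <- file.path(dir, "truth.tsv")
  write_fastq(pairs_to_reads(pairs, 1L), r1_path)
  write_fastq(pairs_to_reads(pairs, 2L), r2_path)
  truth_cols <- c("id1", "template_id", "truth_sample", "barcode", "construct_len",
                  "v6_start1", "v6_end1", "v6_start2_rc", "v6_end2_rc", "insert",
                  "n_err1", "n_err2", "n_v6_err1", "n_v6_err2", "n_N1", "n_N2")
  readr::write_tsv(pairs[truth_cols], truth_path, progress = FALSE)
  invisible(list(r1 = r1_path, r2 = r2_path, truth = truth_path, pairs = pairs))
}

complement_base <- function(b) chartr("ACGTN", "TGCAN", b)

# Redraw until the mutated read keeps its primer anchors: a substitution that
# recreates a primer motif changes the trim coordinates and is no longer an
# error "strictly between the primer sites".
inject_one <- function(sequence, lo, hi, design, forbid_base = NULL) {
  p0 <- find_proximal(sequence, design)$start
  d0 <- find_distal(sequence, design)$start
  for (try in seq_len(50L)) {
    pos <- pick(seq(lo, hi))
    cur <- substr(sequence, pos, pos)
    new <- pick(setdiff(SIM_BASES, c(cur, forbid_base)))
    mutated <- sequence
    substr(mutated, pos, pos) <- new
    p1 <- find_proximal(mutated, design)$start
    d1 <- find_distal(mutated, design)$start
    if (identical(p1, p0) && identical(d1, d0)) {
      return(list(sequence = mutated, pos = pos, base = new))
    }
  }
  abort("could not inject a substitution without disturbing a primer anchor",
        class = "overlapfilter_config_error")
}

#' Inject controlled substitutions into simulated pairs
#'
#' `inject_substitution()` places exactly one substitution strictly between
#' the primer sites of one mate of every pair — the canonical detectable
#' error. `inject_coincident()` places complementary substitutions at the
#' same construct position of *both* mates, so the two reads still agree on
#' the (wrong) sense-strand base — the overlap filter's blind spot. Both
#' redraw the position/base if the mutation would recreate a primer motif
#' and shift the trim coordinates.
#'
#' @param pairs Output of [simulate_pairs()] (truth columns required).
#' @param design The [amplicon_design()] used to simulate.
#' @param mate `"r1"` or `"r2"`: which mate receives the substitution.
#' @param seed Integer seed.
#' @return The pair tibble with mutated sequences plus `inj_pos` (construct
#'   coordinates) and `inj_base`.
#' @export
inject_substitution <- function(pairs, design, mate = c("r1", "r2"), seed) {
  mate <- match.arg(mate)
  read_len <- nchar(pairs$sequence1[1])
  withr::with_seed(derive_seed(seed, 303L), {
    pos <- integer(nrow(pairs))
    base <- character(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      if (mate == "r1") {
        res <- inject_one(pairs$sequence1[i], pairs$v6_start1[i], pairs$v6_end1[i], design)
        pairs$sequence1[i] <- res$sequence
        pos[i] <- res$pos
      } else {
        # mutate in reverse-complement space; report construct coordinates
        rc2 <- reverse_complement(pairs$sequence2[i])
        res <- inject_one(rc2, pairs$v6_start2_rc[i], pairs$v6_end2_rc[i], design)
        pairs$sequence2[i] <- reverse_complement(res$sequence)
        pos[i] <- res$pos + (pairs$construct_len[i] - read_len)
      }
      base[i] <- res$base
    }
    mutate(pairs, inj_pos = pos, inj_base = base)
  })
}

#' @rdname inject_substitution
#' @export
inject_coincident <- function(pairs, design, seed) {
  read_len <- nchar(pairs$sequence1[1])
  withr::with_seed(derive_seed(seed, 404L), {
    pos <- integer(nrow(pairs))
    base <- character(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      offset <- pairs$construct_len[i] - read_len
      for (try in seq_len(50L)) {
        res <- inject_one(pairs$sequence1[i], pairs$v6_start1[i], pairs$v6_end1[i], design)
        rc2 <- reverse_complement(pairs$sequence2[i])
        rc2_pos <- res$pos - offset
        mutated_rc2 <- rc2
        substr(mutated_rc2, rc2_pos, rc2_pos) <- res$base
        p0 <- find_proximal(rc2, design)$start
        d0 <- find_distal(rc2, design)$start
        if (identical(find_proximal(mutated_rc2, design)$start, p0) &&
            identical(find_distal(mutated_rc2, design)$start, d0)) {
          pairs$sequence1[i] <- res$sequence
          pairs$sequence2[i] <- reverse_complement(mutated_rc2)
          pos[i] <- res$pos
          base[i] <- res$base
          break
        }
      }
      if (pos[i] == 0L) {
        abort("could not place a coincident substitution without disturbing a primer anchor",
              class = "overlapfilter_config_error")
      }
    }
    mutate(pairs, inj_pos = pos, inj_base = base)
  })
}
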