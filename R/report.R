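# Diagnostic surfaces: per-sample pass ratios, three-way Venn partition of
# pair fates with per-position mean-quality curves, relative OTU comparison,
# and the information-retention arithmetic. Numeric tables are the source of
# truth; figures are derived from them.

#' Run all three filters on one set of pairs
#'
#' Applies the complete-overlap filter and both Q-score filters to the same
#' pairs and records each pair's fate under each method.
#'
#' @param pairs A pair tibble.
#' @param design An [amplicon_design()].
#' @param bokulich,minoche Parameter sets (defaults: published values).
#' @return A `filter_comparison`: list with the three result tibbles
#'   (`overlap`, `bokulich`, `minoche`) and `fates`, a tibble of verdicts
#'   per pair.
#' @export
compare_filters <- function(pairs, design, bokulich = bokulich_params(),
                            minoche = minoche_params()) {
  ov <- filter_overlap(pairs, design)
  bk <- filter_qscore(pairs, "bokulich", bokulich)
  mn <- filter_qscore(pairs, "minoche", minoche)
  fates <- tibble(id = pairs$id1, overlap = ov$passed,
                  bokulich = bk$passed, minoche = mn$passed)
  structure(list(overlap = ov, bokulich = bk, minoche = mn, fates = fates,
                 design = design),
            class = "filter_comparison")
}

#' @export
print.filter_comparison <- function(x, ...) {
  cat(sprintf("<filter_comparison> %d pairs: overlap %.1f%%, bokulich %.1f%%, minoche %.1f%% passed\n",
              nrow(x$fates), 100 * mean(x$fates$overlap),
              100 * mean(x$fates$bokulich), 100 * mean(x$fates$minoche)))
  invisible(x)
}

#' Three-set Venn partition of pair fates
#'
#' Counts pairs in each of the 8 regions defined by the pass-sets of the
#' three methods (including the all-fail region). Region counts always sum
#' to the number of pairs — asserted on every call.
#'
#' @param fates A tibble with logical columns `overlap`, `bokulich`,
#'   `minoche` (e.g. `compare_filters(...)$fates`), all verdicts present.
#' @return A `venn_partition`: tibble with the three logical columns and
#'   `n`, one row per region.
#' @export
venn_partition <- function(fates) {
  if (inherits(fates, "filter_comparison")) fates <- fates$fates
  methods <- c("overlap", "bokulich", "minoche")
  stopifnot(all(methods %in% names(fates)))
  if (anyNA(fates[methods])) {
    abort("incomplete fate record: every pair needs a verdict from all three methods",
          class = "overlapfilter_incomplete_record")
  }
  grid <- tidyr::expand_grid(overlap = c(TRUE, FALSE), bokulich = c(TRUE, FALSE),
                             minoche = c(TRUE, FALSE))
  counts <- fates |>
    count(.data$overlap, .data$bokulich, .data$minoche, name = "n")
  out <- left_join(grid, counts, by = methods) |>
    mutate(n = tidyr::replace_na(.data$n, 0L))
  stopifnot(sum(out$n) == nrow(fates))
  structure(out, class = c("venn_partition", class(out)))
}

#' Per-position mean quality, by group
#'
#' Mean Phred score at each read position within each group (e.g. a Venn
#' fate region), per quality string. Positions beyond a read's length are
#' excluded from that position's mean; a group with zero reads contributes
#' no rows (not zeros).
#'
#' @param quality Character vector of Phred+33 quality strings.
#' @param group Grouping vector, recycled against `quality`.
#' @return A tibble with `group`, `position`, `mean_q`, `n`.
#' @export
mean_quality_by_position <- function(quality, group = "all") {
  group <- rep_len(as.character(group), length(quality))
  keep <- !is.na(quality)
  quality <- quality[keep]
  group <- group[keep]
  if (!length(quality)) {
    return(tibble(group = character(), position = integer(),
                  mean_q = numeric(), n = integer()))
  }
  decoded <- decode_quality(quality)
  tibble(group = rep(group, lengths(decoded)),
         position = unlist(lapply(decoded, seq_along), use.names = FALSE),
         q = unlist(decoded, use.names = FALSE)) |>
    group_by(.data$group, .data$position) |>
    summarise(mean_q = mean(.data$q), n = n(), .groups = "drop")
}

#' Quality curves for each Venn fate region
#'
#' The companion to [venn_partition()]: per-position mean quality of read 1
#' and read 2, grouped by each pair's pass/fail pattern across the three
#' methods (pattern written as `overlap/bokulich/minoche`, `+` = passed).
#'
#' @param comparison A [compare_filters()] result.
#' @param pairs The pair tibble the comparison was computed from.
#' @return A tibble with `region`, `mate`, `position`, `mean_q`, `n`.
#' @export
quality_by_fate <- function(comparison, pairs) {
  f <- comparison$fates
  region <- paste0(ifelse(f$overlap, "+", "-"), ifelse(f$bokulich, "+", "-"),
                   ifelse(f$minoche, "+", "-"))
  bind_rows(
    mutate(mean_quality_by_position(pairs$quality1, region), mate = "r1"),
    mutate(mean_quality_by_position(pairs$quality2, region), mate = "r2")
  ) |>
    dplyr::rename(region = "group") |>
    select("region", "mate", "position", "mean_q", "n")
}

#' Information retained by complete-overlap filtering
#'
#' A fully overlapping pair sequences every retained base twice, and failed
#' pairs are discarded outright, so the fraction of sequencer output that
#' reaches the final dataset is small. Per passed pair the retained fraction
#' is `100 * trimmed_len / (2 * read_len)`; over the dataset it is
#' additionally scaled by the pass rate. For a 62-nt region in 2x101-nt
#' pairs this gives ~30.7% per pair, and 22.56% for a run passing
#' 2,707,801 of 3,683,211 pairs.
#'
#' @param pairs_total,pairs_passed Pair counts (`pairs_passed <=
#'   pairs_total`, `pairs_total > 0`).
#' @param read_len,trimmed_len Read and retained-region lengths in nt
#'   (`trimmed_len <= 2 * read_len`).
#' @return A one-row tibble with `per_pair_pct` and `dataset_pct`.
#' @export
information_fraction <- function(pairs_total, pairs_passed, read_len, trimmed_len) {
  if (pairs_total <= 0) {
    abort("pairs_total must be positive: the dataset fraction is undefined on an empty run",
          class = "overlapfilter_degenerate_input")
  }
  stopifnot(pairs_passed <= pairs_total, pairs_passed >= 0, trimmed_len <= 2 * read_len)
  tibble(
    per_pair_pct = 100 * trimmed_len / (2 * read_len),
    dataset_pct = 100 * (pairs_passed * trimmed_len) / (pairs_total * 2 * read_len)
  )
}

#' Per-sample pass/fail ratio table
#'
#' The ratio of pairs identified as low quality versus all pairs analysed,
#' per sample and per method. Samples with zero pairs are excluded with a
#' warning.
#'
#' @param comparison A [compare_filters()] result.
#' @param sample Per-pair sample labels (e.g. simulator truth, or the
#'   overlap filter's own demultiplexing).
#' @return A `pass_ratio_table` tibble with `sample`, `method`, `n_pairs`,
#'   `n_passed`, `pass_ratio`, `fail_ratio`.
#' @export
pass_ratio_table <- function(comparison, sample) {
  f <- comparison$fates
  sample <- as.character(rep_len(sample, nrow(f)))
  if (anyNA(sample)) {
    warn(sprintf("%d pairs without a sample label are excluded from the ratio table",
                 sum(is.na(sample))))
  }
  out <- tibble(sample = sample, overlap = f$overlap, bokulich = f$bokulich,
                minoche = f$minoche) |>
    filter(!is.na(.data$sample)) |>
    tidyr::pivot_longer(c("overlap", "bokulich", "minoche"),
                        names_to = "method", values_to = "passed") |>
    group_by(.data$sample, .data$method) |>
    summarise(n_pairs = n(), n_passed = sum(.data$passed), .groups = "drop") |>
    mutate(pass_ratio = .data$n_passed / .data$n_pairs,
           fail_ratio = 1 - .data$pass_ratio)
  structure(out, class = c("pass_ratio_table", class(out)))
}

#' Extract the inter-primer region from single reads
#'
#' Locates both primer anchors on a read and returns the region strictly
#' between them, or `NA` when either anchor is missing. Used to make
#' Q-score-filtered reads comparable with overlap-filtered output before
#' clustering.
#'
#' @param sequences Character vector of reads.
#' @param design An [amplicon_design()].
#' @return Character vector (with `NA`s).
#' @export
extract_insert <- function(sequences, design) {
  out <- rep(NA_character_, length(sequences))
  keep <- !is.na(sequences)
  p <- find_proximal(sequences[keep], design)
  d <- find_distal(sequences[keep], design)
  ok <- !is.na(p$start) & !is.na(d$start) & d$start > p$end
  res <- rep(NA_character_, sum(keep))
  res[ok] <- substr(sequences[keep][ok], p$end[ok] + 1L, d$start[ok] - 1L)
  out[keep] <- res
  out
}

#' Equal-depth OTU comparison across the three filters
#'
#' Collects each method's clusterable reads — the overlap filter's trimmed
#' output, and the inter-primer region of read 1 for pairs passed by each
#' Q-score filter (reads whose anchors cannot be located are dropped) — and
#' runs [subsample_compare()].
#'
#' @param comparison A [compare_filters()] result.
#' @param replicates,threshold,min_size,seed Passed to
#'   [subsample_compare()].
#' @return A `subsample_report`.
#' @export
compare_otus <- function(comparison, replicates = 5L, threshold = 0.97,
                         min_size = 2L, seed) {
  design <- comparison$design
  reads <- list(
    overlap = comparison$overlap$trimmed_sequence[comparison$overlap$passed],
    bokulich = extract_insert(
      comparison$bokulich$trimmed_sequence1[comparison$bokulich$passed], design),
    minoche = extract_insert(
      comparison$minoche$trimmed_sequence1[comparison$minoche$passed], design)
  )
  reads <- lapply(reads, function(x) x[!is.na(x)])
  subsample_compare(reads, replicates = replicates, threshold = threshold,
                    min_size = min_size, seed = seed)
}

# ---- plots -----------------------------------------------------------------

#' @method autoplot venn_partition
#' @export
autoplot.venn_partition <- function(object, ...) {
  circ <- function(cx, cy, r = 1.1, n = 200) {
    t <- seq(0, 2 * pi, length.out = n)
    tibble(x = cx + r * cos(t), y = cy + r * sin(t))
  }
  centers <- tibble(set = c("overlap", "bokulich", "minoche"),
                    cx = c(0, 1.2, 0.6), cy = c(0, 0, 1.0))
  # region label coordinates keyed by pass pattern (overlap, bokulich, minoche)
  lab <- tibble(
    overlap = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    bokulich = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    minoche = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
    x = c(0.6, 0.6, 0.1, -0.45, 1.1, 1.65, 0.6, 2.6),
    y = c(0.35, -0.35, 0.55, -0.35, 0.55, -0.35, 1.45, 1.6)
  )
  dat <- dplyr::left_join(as_tibble(object), lab,
                          by = c("overlap", "bokulich", "minoche"))
  circles <- bind_rows(lapply(seq_len(3), function(i) {
    mutate(circ(centers$cx[i], centers$cy[i]), set = centers$set[i])
  }))
  ggplot2::ggplot() +
    ggplot2::geom_path(data = circles,
                       ggplot2::aes(x = .data$x, y = .data$y, colour = .data$set)) +
    ggplot2::geom_text(data = dat,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$n)) +
    ggplot2::geom_text(data = centers,
                       ggplot2::aes(x = .data$cx, y = .data$cy + 1.25,
                                    label = .data$set, colour = .data$set)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none") +
    ggplot2::labs(title = "Pair fates across filtering methods",
                  subtitle = "count outside all circles = failed by every method")
}

#' @method autoplot pass_ratio_table
#' @export
autoplot.pass_ratio_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sample, y = .data$fail_ratio,
                                       fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "fraction of pairs identified as low quality",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @method autoplot subsample_report
#' @export
autoplot.subsample_report <- function(object, ...) {
  long <- glance(object) |>
    tidyr::pivot_longer(c("ratio", "mean_otus"), names_to = "metric") |>
    mutate(metric = dplyr::recode(.data$metric, ratio = "relative OTUs (max = 1)",
                                  mean_otus = "mean OTUs"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$value,
                                     fill = .data$method)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Per-position mean quality curves, one line per group
#'
#' @param data Output of [mean_quality_by_position()] or [quality_by_fate()].
#' @return A ggplot object.
#' @export
plot_quality_curves <- function(data) {
  grp <- if ("region" %in% names(data)) "region" else "group"
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$position, y = .data$mean_q,
                                          colour = .data[[grp]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "read position", y = "mean Q", colour = NULL) +
    ggplot2::theme_minimal()
  if ("mate" %in% names(data)) p <- p + ggplot2::facet_wrap(~mate)
  p
}
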