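# Greedy identity-threshold OTU clustering and the equal-depth subsampling
# protocol used to contrast filtering methods. This is a documented
# approximation of abundance-sorted greedy centroid clustering (the UCLUST
# family), not a re-implementation of any particular tool's heuristics: the
# quantity of interest — relative OTU inflation across filters — depends on
# greedy threshold clustering generically.

#' Pairwise sequence identity
#'
#' `1 - edit_distance(a, b) / max(nchar(a), nchar(b))`. Normalising by the
#' longer length keeps variable-length reads (quality trimming produces
#' them) comparable; for equal-length substitution-only pairs this is
#' exactly one minus the substitution fraction. At a 97% threshold,
#' ~62-nt reads cluster together at one substitution (identity 61/62) and
#' split at two (60/62).
#'
#' @param a,b Character vectors (recycled to a common length).
#' @return Numeric vector of identities in `[0, 1]`.
#' @export
seq_identity <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  stopifnot(all(nchar(a) > 0), all(nchar(b) > 0))
  d <- vapply(seq_len(n), function(i) adist(a[i], b[i])[1, 1], numeric(1))
  1 - d / pmax(nchar(a), nchar(b))
}

#' Greedy identity-threshold clustering
#'
#' Dereplicates exact duplicates, orders the unique sequences by abundance
#' (descending; ties broken lexicographically, so input order never
#' matters), then scans in order assigning each sequence to the first
#' already-founded representative with identity at or above `threshold`, or
#' founding a new cluster. Clusters smaller than `min_size` are flagged as
#' not retained. At `threshold = 1` this reduces exactly to dereplication
#' with a minimum-abundance cut.
#'
#' @param reads Character vector of sequences.
#' @param threshold Identity threshold in `(0, 1]` (default 0.97).
#' @param min_size Minimum cluster size after clustering (default 2).
#' @return A `cluster_set` object; see [tidy.cluster_set()] /
#'   [glance.cluster_set()].
#' @export
cluster_greedy <- function(reads, threshold = 0.97, min_size = 2L) {
  stopifnot(threshold > 0, threshold <= 1, min_size >= 1)
  if (!length(reads)) {
    clusters <- tibble(representative = character(), size = integer(), retained = logical())
    return(new_cluster_set(clusters, threshold, min_size, 0L))
  }
  tab <- table(reads)
  uniq <- names(tab)
  cnts <- as.integer(tab)
  ord <- order(-cnts, uniq)
  uniq <- uniq[ord]
  cnts <- cnts[ord]

  reps <- character(0)
  sizes <- integer(0)
  for (i in seq_along(uniq)) {
    j <- NA_integer_
    if (length(reps)) {
      if (threshold == 1) {
        # identity 1 requires exact equality; uniques are distinct by construction
      } else {
        d <- drop(adist(uniq[i], reps))
        idv <- 1 - d / pmax(nchar(uniq[i]), nchar(reps))
        j <- which(idv >= threshold)[1]
      }
    }
    if (is.na(j)) {
      reps <- c(reps, uniq[i])
      sizes <- c(sizes, cnts[i])
    } else {
      sizes[j] <- sizes[j] + cnts[i]
    }
  }
  clusters <- tibble(representative = reps, size = sizes,
                     retained = sizes >= min_size) |>
    arrange(dplyr::desc(.data$size), .data$representative)
  new_cluster_set(clusters, threshold, min_size, length(reads))
}

new_cluster_set <- function(clusters, threshold, min_size, n_reads) {
  structure(
    list(clusters = clusters, threshold = threshold,
         min_size = as.integer(min_size), n_reads = as.integer(n_reads)),
    class = "cluster_set"
  )
}

#' Number of retained OTUs in a cluster set
#' @param x A `cluster_set`.
#' @return Integer count of clusters meeting the minimum size.
#' @export
n_otus <- function(x) {
  stopifnot(inherits(x, "cluster_set"))
  sum(x$clusters$retained)
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d reads -> %d clusters (%d retained at min size %d), threshold %.2f\n",
              x$n_reads, nrow(x$clusters), n_otus(x), x$min_size, x$threshold))
  invisible(x)
}

#' Tidiers for cluster sets
#'
#' `tidy()` returns one row per retained cluster (set `all = TRUE` for every
#' cluster including sub-minimum ones); `glance()` a one-row summary.
#'
#' @param x A `cluster_set`.
#' @param all Include clusters below the minimum size?
#' @param ... Unused.
#' @method tidy cluster_set
#' @export
tidy.cluster_set <- function(x, all = FALSE, ...) {
  if (all) x$clusters else filter(x$clusters, .data$retained)
}

#' @rdname tidy.cluster_set
#' @method glance cluster_set
#' @export
glance.cluster_set <- function(x, ...) {
  tibble(n_reads = x$n_reads, n_unique_clusters = nrow(x$clusters),
         n_otus = n_otus(x), threshold = x$threshold, min_size = x$min_size)
}

#' Equal-depth subsampling comparison of filtering methods
#'
#' The methods under comparison rarely keep the same number of reads, and
#' OTU counts grow with depth, so each method's read list is randomly
#' subsampled (without replacement) to the smallest method's depth before
#' clustering; `replicates` independent subsamples (default 5) are clustered
#' and the per-method mean OTU count reported, normalised so the method with
#' the largest mean has relative ratio 1.0. The method already at minimum
#' depth is clustered once and its count repeated, since subsampling it is
#' the identity. Random streams are derived from `(seed, method index,
#' replicate index)`, so adding a method never perturbs another's
#' subsamples.
#'
#' @param method_reads Named list (>= 2 entries) of character vectors of
#'   reads, one per filtering method.
#' @param replicates Number of subsampling replicates.
#' @param threshold,min_size Passed to [cluster_greedy()].
#' @param seed Integer seed; mandatory for reproducibility.
#' @return A `subsample_report`; see [tidy.subsample_report()].
#' @export
subsample_compare <- function(method_reads, replicates = 5L, threshold = 0.97,
                              min_size = 2L, seed) {
  stopifnot(is.list(method_reads), length(method_reads) >= 2L,
            !is.null(names(method_reads)), replicates >= 1L)
  sizes <- lengths(method_reads)
  if (any(sizes == 0L)) {
    abort(sprintf("method \"%s\" has zero reads; nothing to subsample",
                  names(method_reads)[sizes == 0L][1]),
          class = "overlapfilter_degenerate_input")
  }
  depth <- min(sizes)
  rows <- purrr::imap(method_reads, function(reads, m) {
    i <- match(m, names(method_reads))
    if (length(reads) == depth) {
      cs <- cluster_greedy(reads, threshold, min_size)
      tibble(method = m, replicate = seq_len(replicates), n_otus = n_otus(cs))
    } else {
      counts <- vapply(seq_len(replicates), function(j) {
        sub <- withr::with_seed(derive_seed(seed, i, j),
                                sample(reads, depth, replace = FALSE))
        n_otus(cluster_greedy(sub, threshold, min_size))
      }, integer(1))
      tibble(method = m, replicate = seq_len(replicates), n_otus = counts)
    }
  })
  results <- bind_rows(rows)
  summary <- results |>
    group_by(.data$method) |>
    summarise(mean_otus = mean(.data$n_otus), .groups = "drop") |>
    mutate(ratio = .data$mean_otus / max(.data$mean_otus))
  structure(
    list(results = results, summary = summary, depth = as.integer(depth),
         replicates = as.integer(replicates), threshold = threshold,
         min_size = as.integer(min_size), seed = seed),
    class = "subsample_report"
  )
}

#' @export
print.subsample_report <- function(x, ...) {
  cat(sprintf("<subsample_report> depth %d, %d replicates, threshold %.2f\n",
              x$depth, x$replicates, x$threshold))
  print(x$summary)
  invisible(x)
}

#' Tidiers for subsampling reports
#'
#' `tidy()` returns per-replicate OTU counts; `glance()` per-method means
#' and relative ratios (largest mean = 1.0).
#'
#' @param x A `subsample_report`.
#' @param ... Unused.
#' @method tidy subsample_report
#' @export
tidy.subsample_report <- function(x, ...) x$results

#' @rdname tidy.subsample_report
#' @method glance subsample_report
#' @export
glance.subsample_report <- function(x, ...) {
  mutate(x$summary, depth = x$depth, replicates = x$replicates,
         threshold = x$threshold)
}
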